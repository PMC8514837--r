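Package: tbprobe
Title: Retroauricular Temporal Bone Thickness and Density Mapping from CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated morphometry of the retroauricular temporal bone from
    calibrated computed-tomography volumes, for preoperative planning of
    screw and implant placement in otologic and robotic ear surgery. From a
    CT volume in Hounsfield units and three anatomical landmarks (Henle's
    spine and two points on the zygomatic process) the package segments
    bone, extracts a smoothed outer-surface mesh, builds an anatomy-based
    retroauricular coordinate system with an 8 x 8 probe grid, samples
    radiodensity along surface-normal trajectories, and derives per-probe
    bone thickness, cortical bone density, the Screw Implantation Safety
    Index (SISI) and the Column Density Index (CODI). Includes phantom-based
    Hounsfield-unit to bone-mineral-density calibration, a synthetic CT
    phantom generator with analytic ground truth for validation, cohort
    grid aggregation and heat-map reporting, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
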