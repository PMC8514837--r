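---
title: "Methods: retroauricular bone thickness and density probing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retroauricular bone thickness and density probing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbprobe)
```

## The measurement model

`tbprobe` quantifies two properties of the retroauricular temporal bone
that jointly determine whether a location can hold a surgical screw: the
available bone thickness and the radiodensity (calibrated to bone mineral
density) along the insertion axis. The measurement is a ray-probing scheme
on a segmented bone surface:

* The bone is labeled by an inclusive threshold, HU ≥ 620 (the compact-bone
  threshold). Inclusivity is a deliberate choice — "at least" semantics make
  the boundary case deterministic and testable.
* Disconnected islands under 300 voxels are removed with 26-connectivity.
  The cutoff acts on the foreground only; 26-connectivity is the common
  choice for speckle removal in 3D masks, and the comparison is strict
  ("fewer than 300"), so a 300-voxel component survives.
* The outer surface is extracted as the isosurface of the binary mask.
  We use marching tetrahedra (each cell split into six tetrahedra around a
  consistent main diagonal): it belongs to the same isosurface family as
  marching cubes but is watertight by construction on binary data, with no
  ambiguous cube cases. Vertices fall on the midpoints of grid edges, i.e.
  half a voxel outside the outermost labeled voxel center — exactly the
  midpoint between bone and air voxel centers.
* The mesh is low-pass filtered with a Taubin λ|μ filter (λ = 0.5,
  μ = −0.53), a non-shrinking smoother. The `smoothing_mm` parameter
  (default 4 mm) is interpreted as the width of an equivalent Gaussian
  kernel with σ = `smoothing_mm`/2; since one Laplacian step of factor λ on
  a mesh with mean edge length h diffuses with step variance ≈ λh², the
  iteration count is σ²/(λh²), capped at 500. `smoothing_mm = 0` returns
  the raw isosurface unchanged. Non-shrinkage matters: a shrinking filter
  would bias every thickness measurement downward.

## Coordinate conventions

All computation happens in physical millimetre coordinates in a canonical
RAS-like orientation. NIfTI volumes are reoriented to the closest RAS
layout on read; DICOM geometry (LPS) is converted by negating x and y.
Voxel indices are 0-based and address voxel *centers*; this makes the
trajectory sampling arithmetic exact (`position = origin + axes · (i·s_x,
j·s_y, k·s_z)`), and round trips are identity to 10⁻⁹ mm.

The anatomical frame uses three landmarks identifiable in situ: the most
superior point of Henle's spine (origin) and two points along the center of
the zygomatic process. The y-axis is the axial-plane normal oriented
superiorly — this realizes "the x/y-plane is perpendicular to the
transversal image plane" with the minimal assumption, and is a documented
convention, not a derived quantity. The x-axis is the zygomatic direction
projected into the axial plane; when the zygomatic direction has a large
out-of-plane component this projection is our choice of realization, and a
direction parallel to the axial normal is rejected as degenerate. The sign
of x is fixed posteriorly by a `posterior_hint` unit vector (default:
scanner posterior) rather than by the input point order, so the frame is
invariant to swapping the two zygomatic landmarks, and the hint rotates
with the landmarks, preserving rotation covariance. Left ears mirror the
lateral axis so +x is posterior and +z lateral on both sides; the left
frame is therefore left-handed by construction, which permits pooling left
and right ears in one grid.

## Probing and derived quantities

Grid points (default 8 × 8, 5 mm spacing, corner (4, −10) mm) are cast
along −z (medially). The first triangle hit is the entry point, and the
trajectory follows that triangle's *inward* normal — the local insertion
axis — not the grid ray. Radiodensity is sampled by trilinear interpolation
every Δd = 0.15 mm (nearest-voxel reads are available as an option; the
choice between them is an interpolation convention, and trilinear is the
smoother default at 0.156–0.2 mm voxels).

Thickness d_TB is the distance from the entry point to the *farthest*
ray–mesh intersection within the 18 mm cap. Taking the farthest hit makes
internal air-cell walls transparent to the thickness measurement, which is
the intended outer-to-inner-cortex distance. Three boundary policies are
explicit:

* a far surface beyond 18 mm clamps d_TB to 18 mm;
* a ray with no further intersection at all (exiting the open side of a
  cropped mesh) also reports the 18 mm cap, with a warning rather than a
  discarded probe;
* profiles are never sampled past d_TB, so the cap also truncates the CODI
  summation range.

Cortical density averages the samples in the window [onset, onset + 1.5 mm],
inclusive at both ends (11 samples when the onset aligns with a sample),
where the onset is the first sample ≥ 1000 HU. If no sample reaches
1000 HU the probe reports "no cortex" rather than a number. The window is
1.5 mm; the averaging is done on raw HU and only the final mean is
converted to mg HA/cm³, so a calibration change never re-enters the profile
arithmetic. The window length is a configuration field.

## Indices

For a screw length d_min (defaults 4 and 5 mm):

* **SISI** = 0 if d_TB ≤ d_min, else 100·N_S/N, with both counts over
  samples at depth ≤ d_min. N deliberately counts *all* samples — air
  inside mastoid cells dilutes the index, which is the point of the score.
  "At least 1,000 HU" is inclusive.
* **CODI** = Σ ρ_TB(i)·Δd over the full d_TB (capped at 18 mm). Calibrated
  densities are carried in mg HA/cm³ and divided by 1000 to mg HA/mm³
  before multiplying by Δd in mm, giving mg HA/mm². This unit bridge is an
  implementation decision; the defining sum is otherwise stated over the
  full bone thickness, and a d_min-bounded variant is exposed as an option
  (`codi(..., bound = "d_min")`).

## Calibration

`fit_calibration` is an ordinary least-squares line HU = slope·ρ +
intercept over the six insert measurements (0/water through 800 mg HA/cm³);
a table with fewer than two distinct densities is a degenerate fit and an
error. Conversion clamps negative HU to zero *before* the linear map and
floors the result at zero, so calibrated densities are always non-negative
and non-decreasing in HU. When no phantom table is supplied the pipeline
falls back to the published slope of 1.32 with zero intercept and says so
in a message: the slope is protocol-specific, so the fallback is a
convenience for uncalibrated scans, not a calibration.

## The synthetic phantoms

The generator builds the study's test conditions, not arbitrary scenes:

* **Slabs** use the clinical voxel grid (0.156 × 0.156 × 0.2 mm³) by
  default, layers listed from the probed surface inward, embedded in
  −1000 HU air with ~3 mm clearance. Layer interfaces are snapped to voxel
  boundaries and the realized geometry is recorded as ground truth — the
  truth is what was actually built, and clinically relevant thicknesses
  (multiples of 0.2 mm) are then exactly representable. The default layered
  slab is 2 mm cortex (1500 HU), 6 mm trabecular bone (300 HU), 2 mm
  cortex.
* **Air cells** are spherical voids at −800 HU (aerated, mucosa-lined
  cells; the value is conventional) with default radius 1 mm, a realistic
  mastoid cell size. Centers follow a Poisson process in the r-dilated
  layer so the covered fraction inside the layer is uniform and equals the
  requested Boolean-model fraction 1 − e^(−λV).
* **Noise** is additive Gaussian HU noise, a reasonable model at clinical
  dose; everything is seeded, and an identical spec + seed reproduces the
  volume bit for bit.
* The **calibration phantom** provides six cylindrical inserts in a
  water-equivalent body at 0.5 mm voxels, with measured (not assumed)
  per-insert mean HU returned as the insert table.

What the phantoms deliberately do not emulate: curved anatomy, cortical
thickness gradients, beam hardening, partial-volume behavior beyond
trilinear sampling, or scanner-specific noise texture. Passing the phantom
suite therefore demonstrates the correctness of the geometry, sampling and
index arithmetic — not clinical accuracy on real temporal bones, which
depends on segmentation quality and calibration validity for the scanner at
hand.

## Numerical choices and degenerate inputs

* Ray–mesh intersection uses Möller–Trumbore with a 10⁻¹² determinant
  cutoff and 10⁻⁹ barycentric slack; hits under 10⁻⁶ mm are treated as the
  entry point itself.
* Trilinear interpolation clamps to the voxel-extent boundary within the
  outer half-voxel border; positions beyond it are NA and terminate the
  profile.
* Probes that miss the mesh report status `no_intersection` and keep their
  row (empty fields) in the CSV; aggregation counts them out of the cell
  mean instead of zero-filling.
* The test problem sizes — slabs of 10–50 mm lateral extent, 2–25 mm
  thickness, a 27³ sphere, 10⁴-voxel calibration inserts — were chosen as
  the smallest geometries on which each property is non-trivial (e.g. a
  sphere radius of ten voxels for curvature, interfaces crossing many
  voxels for partial-volume behavior).

## Known limitations

Thickness at very oblique local normals can reach the cap through the path
length alone (a 10 mm slab probed at 60° measures 20 mm → 18 mm); this is
inherent to the definition, which measures along the insertion axis, not
the shortest caliper distance. The cortical window mixes in the
partial-volume shoulder at coarse voxel sizes, biasing the cortical mean
slightly low (visible in the README example at 0.5 mm voxels, and about an
order of magnitude smaller at the clinical spacing). Cohort-level clinical
statements (thickness gradients, side differences, the location of the
CODI maximum) require clinical scans and mixed-effects modeling, which are
outside this package's scope — the per-probe CSVs are written so that such
models can be fitted directly with `lme4` or similar.
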