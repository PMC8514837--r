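# Probe projection and trajectory sampling. Each grid point is cast along
# -z (medially) onto the outer bone surface; from the hit point a trajectory
# follows the hit triangle's inward normal. Radiodensity is sampled every
# delta_d = 0.15 mm; temporal bone thickness d_TB is the distance to the
# last (farthest) mesh intersection, capped at 18 mm; cortical density is
# the mean HU over a 1.5 mm window starting at the first sample >= 1000 HU.

#' Project a grid point onto the bone mesh
#'
#' Casts a ray from the grid point along the frame's -z axis (medially) and
#' returns the first surface hit together with the inward unit normal of the
#' hit triangle, which defines the trajectory direction.
#'
#' @param grid_point Frame (x, y) coordinates of the probe (mm).
#' @param mesh A `bone_mesh`.
#' @param frame A `retro_frame`.
#' @return List with `status` (`"ok"` or `"no_intersection"`), and for hits
#'   `entry_point` (physical mm), `direction` (inward unit normal) and
#'   `triangle` (1-based face index).
#' @export
project_probe <- function(grid_point, mesh, frame) {
  stopifnot(inherits(mesh, "bone_mesh"), inherits(frame, "retro_frame"))
  # start laterally beyond the mesh so the first hit is the outer surface
  vz <- to_frame(frame, mesh$vertices)[, 3]
  z0 <- max(vz) + 1
  orig <- as.numeric(from_frame(frame, c(grid_point[1], grid_point[2], z0)))
  dir <- -frame$z_axis
  hits <- ray_hits_cpp(mesh$vertices, mesh$faces - 1L, orig, dir)
  fwd <- hits$t > 1e-9
  if (!any(fwd)) return(list(status = "no_intersection"))
  i <- which(fwd)[1]
  tri <- hits$triangle[i] + 1L
  inward <- -mesh$normals[tri, ]
  list(status = "ok",
       entry_point = orig + hits$t[i] * dir,
       direction = inward / sqrt(sum(inward^2)),
       triangle = tri)
}

#' Temporal bone thickness along a trajectory
#'
#' Distance from the entry point to the last ray-mesh intersection along the
#' trajectory, capped at `d_max`. Intersections beyond `d_max` clamp the
#' thickness to `d_max`; internal surfaces (air-cell walls) crossed before
#' the far cortex do not shorten the measurement because the farthest hit
#' wins. If the ray leaves the mesh without any further intersection the cap
#' is returned with a warning (`opposite_found = FALSE`).
#'
#' @param mesh A `bone_mesh`.
#' @param entry_point Physical entry position on the surface (mm).
#' @param direction Unit trajectory direction (into the bone).
#' @param d_max Thickness cap in mm (default 18).
#' @return List with `d_tb` (mm) and `opposite_found` (logical).
#' @export
thickness <- function(mesh, entry_point, direction, d_max = 18) {
  hits <- ray_hits_cpp(mesh$vertices, mesh$faces - 1L,
                       as.numeric(entry_point), as.numeric(direction))
  tt <- hits$t[hits$t > 1e-6]
  within <- tt[tt <= d_max]
  if (length(within)) return(list(d_tb = max(within), opposite_found = TRUE))
  if (length(tt)) return(list(d_tb = d_max, opposite_found = TRUE))
  warning("thickness: no opposite surface intersection; returning the ",
          d_max, " mm cap")
  list(d_tb = d_max, opposite_found = FALSE)
}

#' Sample radiodensity along a trajectory
#'
#' Samples HU at `entry_point + k * delta_d * direction`, k = 0, 1, ...,
#' stopping at `d_max` or at the volume boundary. Sample depths strictly
#' increase by `delta_d` and never exceed `d_max`.
#'
#' @param volume A [ct_volume].
#' @param entry_point Physical start position (mm); must lie inside the
#'   volume.
#' @param direction Unit direction.
#' @param delta_d Sampling interval (mm), default 0.15.
#' @param d_max Maximum depth (mm), default 18.
#' @param method Interpolation: `"trilinear"` (default) or `"nearest"`.
#' @return Numeric vector of HU samples; sample `k+1` lies at depth
#'   `k * delta_d`.
#' @export
sample_profile <- function(volume, entry_point, direction, delta_d = 0.15,
                           d_max = 18, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  entry_point <- as.numeric(entry_point)
  direction <- as.numeric(direction)
  depths <- seq(0, d_max + 1e-9, by = delta_d)
  depths <- depths[depths <= d_max + 1e-9]
  pts <- outer(depths, direction) + rep(entry_point, each = length(depths))
  hu <- interp_hu(volume, pts, method = method)
  if (is.na(hu[1]))
    stop("sample_profile: entry point lies outside the volume")
  bad <- which(is.na(hu))
  if (length(bad)) hu <- hu[seq_len(bad[1] - 1L)]
  hu
}

#' Cortical bone density from a sampled profile
#'
#' Locates the first sample with radiodensity at least `onset_hu` and
#' averages the samples within `[onset, onset + window_mm]` (both ends
#' inclusive; 11 samples at 0.15 mm spacing). The window is truncated if the
#' profile ends first. If no sample reaches the onset threshold the probe
#' has no measurable cortex.
#'
#' @param samples Numeric HU profile from [sample_profile()].
#' @param delta_d Sampling interval (mm).
#' @param onset_hu Cortical onset threshold (HU), default 1000.
#' @param window_mm Averaging window (mm), default 1.5.
#' @return List with `status` (`"ok"` or `"no_cortex"`), `cortical_hu`
#'   (mean HU, `NA` when no cortex), `onset_index` (1-based sample index).
#' @export
cortical_density <- function(samples, delta_d = 0.15, onset_hu = 1000,
                             window_mm = 1.5) {
  if (length(samples) == 0L)
    stop("cortical_density: empty profile")
  onset <- which(samples >= onset_hu)[1]
  if (is.na(onset))
    return(list(status = "no_cortex", cortical_hu = NA_real_,
                onset_index = NA_integer_))
  last <- onset + floor(window_mm / delta_d + 1e-9)
  last <- min(last, length(samples))
  list(status = "ok", cortical_hu = mean(samples[onset:last]),
       onset_index = onset)
}

#' Evaluate one probe end to end
#'
#' Projects the grid point, measures thickness, samples the trajectory over
#' the measured thickness (never past `d_max`) and computes the cortical
#' density. The returned profile carries everything the indices need.
#'
#' @param grid_point Frame (x, y) of the probe (mm).
#' @param volume A [ct_volume].
#' @param mesh A `bone_mesh`.
#' @param frame A `retro_frame`.
#' @param delta_d Sampling interval (mm).
#' @param d_max Thickness cap (mm).
#' @param onset_hu Cortical onset threshold (HU).
#' @param window_mm Cortical averaging window (mm).
#' @param method Interpolation method for [sample_profile()].
#' @return A `probe_profile`: list with `grid_xy`, `status`, `entry_point`,
#'   `direction`, `samples`, `delta_d`, `d_tb`, `cortical_hu`.
#' @export
probe_profile <- function(grid_point, volume, mesh, frame, delta_d = 0.15,
                          d_max = 18, onset_hu = 1000, window_mm = 1.5,
                          method = "trilinear") {
  pr <- project_probe(grid_point, mesh, frame)
  if (pr$status != "ok")
    return(structure(list(grid_xy = as.numeric(grid_point),
                          status = "no_intersection"),
                     class = "probe_profile"))
  th <- suppressWarnings(thickness(mesh, pr$entry_point, pr$direction, d_max))
  samples <- sample_profile(volume, pr$entry_point, pr$direction,
                            delta_d = delta_d, d_max = min(th$d_tb, d_max),
                            method = method)
  cort <- cortical_density(samples, delta_d, onset_hu, window_mm)
  structure(list(grid_xy = as.numeric(grid_point), status = "ok",
                 entry_point = pr$entry_point, direction = pr$direction,
                 samples = samples, delta_d = delta_d, d_tb = th$d_tb,
                 opposite_found = th$opposite_found,
                 cortical_hu = cort$cortical_hu,
                 cortical_status = cort$status),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat("Probe at frame (", paste(signif(x$grid_xy, 5), collapse = ", "),
      ") mm: ", x$status, "\n", sep = "")
  if (x$status == "ok")
    cat("  d_TB", signif(x$d_tb, 5), "mm;", length(x$samples), "samples;",
        "cortical", signif(x$cortical_hu, 6), "HU\n")
  invisible(x)
}

#' Construct a probe profile from raw samples
#'
#' Convenience constructor for synthetic profiles (testing, analytic ground
#' truth): no geometry, just the sampled sequence, its spacing and the
#' associated thickness.
#'
#' @param samples Numeric HU samples at `delta_d` spacing, starting at the
#'   bone surface.
#' @param delta_d Sampling interval (mm).
#' @param d_tb Temporal bone thickness (mm); default: depth of the last
#'   sample.
#' @return A `probe_profile` with status `"ok"`.
#' @export
synthetic_profile <- function(samples, delta_d = 0.15,
                              d_tb = (length(samples) - 1) * delta_d) {
  structure(list(grid_xy = c(NA_real_, NA_real_), status = "ok",
                 samples = as.numeric(samples), delta_d = delta_d,
                 d_tb = d_tb, opposite_found = TRUE,
                 cortical_hu = NA_real_, cortical_status = "ok"),
            class = "probe_profile")
}

#' Evaluate all probes of a grid and tabulate results
#'
#' Runs [probe_profile()] for every grid point and computes the indices,
#' returning one row per probe. Probes that miss the mesh keep their row
#' with `NA` measurements and status `"no_intersection"`.
#'
#' @param volume A [ct_volume].
#' @param mesh A `bone_mesh`.
#' @param grid A `probe_grid` (carries its frame).
#' @param calibration A `calibration_model`; default the published slope.
#' @param subject Subject identifier stored in the table.
#' @param d_min Numeric vector of screw-length thresholds (mm) for SISI.
#' @param delta_d,d_max,onset_hu,window_mm,method Passed to
#'   [probe_profile()].
#' @return Data frame (class `probe_table`) with columns `subject`,
#'   `grid_x`, `grid_y`, `d_tb_mm`, `cortical_hu`, `cortical_bmd`,
#'   `sisi_<d_min>` per threshold, `codi`, `status`.
#' @export
probe_table <- function(volume, mesh, grid, calibration = default_calibration(),
                        subject = "subject1", d_min = c(4, 5),
                        delta_d = 0.15, d_max = 18, onset_hu = 1000,
                        window_mm = 1.5, method = "trilinear") {
  stopifnot(inherits(grid, "probe_grid"))
  frame <- grid$frame
  rows <- lapply(seq_len(nrow(grid$points)), function(i) {
    gp <- grid$points[i, ]
    prof <- probe_profile(gp, volume, mesh, frame, delta_d = delta_d,
                          d_max = d_max, onset_hu = onset_hu,
                          window_mm = window_mm, method = method)
    base <- data.frame(subject = subject, grid_x = gp[1], grid_y = gp[2])
    if (prof$status != "ok") {
      meas <- data.frame(d_tb_mm = NA_real_, cortical_hu = NA_real_,
                         cortical_bmd = NA_real_)
      ss <- as.list(rep(NA_real_, length(d_min)))
      codi_val <- NA_real_
    } else {
      meas <- data.frame(
        d_tb_mm = prof$d_tb,
        cortical_hu = prof$cortical_hu,
        cortical_bmd = if (is.na(prof$cortical_hu)) NA_real_ else
          hu_to_bmd(calibration, prof$cortical_hu))
      ss <- lapply(d_min, function(dm) sisi(prof, dm, dense_hu = onset_hu))
      codi_val <- codi(prof, calibration)
    }
    names(ss) <- paste0("sisi_", d_min)
    cbind(base, meas, as.data.frame(ss), codi = codi_val,
          status = prof$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("probe_table", "data.frame")
  attr(out, "grid") <- grid[c("nx", "ny", "spacing", "corner")]
  out
}
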