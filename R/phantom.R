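# Synthetic CT phantoms with analytic ground truth. Two kinds:
#   * layered bone slabs (cortical/trabecular layers, optional pneumatized
#     air cells, optional Gaussian HU noise) embedded in air, for validating
#     segmentation, meshing, probing and the indices;
#   * the six-insert density calibration phantom (water + 100..800
#     mg HA/cm^3) for validating the HU/BMD fit.
# Conventions: air -1000 HU, water 0 HU, mastoid air cells -800 HU
# (aerated mucosa-lined cells). Layer interfaces are snapped to voxel
# boundaries along z so the realized geometry is exactly representable; the
# ground truth records the realized values. Identical spec + seed give
# bitwise-identical volumes.

#' Specify a synthetic phantom
#'
#' @param kind `"slab"`, `"layered_slab"` or `"calibration"`.
#' @param dim_mm Physical extent (mm), length 3. Default `c(20, 20, 24)` for
#'   slabs, `c(60, 40, 20)` for the calibration phantom.
#' @param spacing Voxel size (mm); default the clinical protocol
#'   `c(0.156, 0.156, 0.2)` for slabs and 0.5 mm isotropic for the
#'   calibration phantom.
#' @param layers List of `list(thickness, hu)` pairs, ordered from the outer
#'   surface inward. Default: a single 10 mm layer at 1500 HU for
#'   `"slab"`; 2 mm cortex at 1500 HU, 6 mm trabecular bone at 300 HU, 2 mm
#'   cortex at 1500 HU for `"layered_slab"`.
#' @param air_cell_params `NULL` or `list(radius, fraction, layer, hu)`:
#'   spherical air cells of the given radius (mm, default 1) occupying the
#'   given volume fraction (in `[0, 1)`) of the given layer (default 2),
#'   at `hu` (default -800).
#' @param noise_sd Additive Gaussian HU noise SD (default 0, noiseless).
#' @param seed Integer seed controlling air-cell placement and noise.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("slab", "layered_slab", "calibration"),
                         dim_mm = NULL, spacing = NULL, layers = NULL,
                         air_cell_params = NULL, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(spacing))
    spacing <- if (kind == "calibration") c(0.5, 0.5, 0.5) else
      c(0.156, 0.156, 0.2)
  if (is.null(dim_mm))
    dim_mm <- if (kind == "calibration") c(60, 40, 20) else c(20, 20, 24)
  if (is.null(layers))
    layers <- switch(kind,
      slab = list(list(thickness = 10, hu = 1500)),
      layered_slab = list(list(thickness = 2, hu = 1500),
                          list(thickness = 6, hu = 300),
                          list(thickness = 2, hu = 1500)),
      calibration = list())
  if (kind != "calibration") {
    th <- vapply(layers, `[[`, numeric(1), "thickness")
    if (any(th <= 0)) stop("phantom_spec: layer thicknesses must be positive")
  }
  if (!is.null(air_cell_params)) {
    air_cell_params <- utils::modifyList(
      list(radius = 1, fraction = 0.3, layer = 2L, hu = -800),
      air_cell_params)
    if (air_cell_params$fraction < 0 || air_cell_params$fraction >= 1)
      stop("phantom_spec: air-cell volume fraction must be in [0, 1)")
  }
  structure(list(kind = kind, dim_mm = as.numeric(dim_mm),
                 spacing = as.numeric(spacing), layers = layers,
                 air_cell_params = air_cell_params,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

with_phantom_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a layered bone slab phantom
#'
#' The slab spans the full lateral (x, y) extent, stacked along z with the
#' first layer at the top (+z, the probed side) and air (-1000 HU) above and
#' below. The ground truth records the realized layer interfaces, the
#' analytic perpendicular-probe HU profile, and the indices that an ideal
#' perpendicular probe yields under the default analysis parameters.
#'
#' @param spec A `phantom_spec` of kind `"slab"` or `"layered_slab"`.
#' @param calibration Calibration model used for the analytic ground-truth
#'   CODI (default the published slope).
#' @return List (class `slab_phantom`) with `volume` (a [ct_volume]) and
#'   `truth`: `z_top`, `z_bottom`, `interfaces` (physical z of each layer
#'   interface, top down), `layer_hu`, `thickness` (realized total, mm),
#'   `profile_fun(depths)` (analytic HU vs depth from the top surface,
#'   ignoring air cells and noise), `d_tb`, `cortical_hu`, `sisi`
#'   (named, d_min 4 and 5), `codi`.
#' @export
generate_slab <- function(spec, calibration = default_calibration()) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind != "calibration")
  sp <- spec$spacing
  nvox <- pmax(round(spec$dim_mm / sp), 2L)
  th <- vapply(spec$layers, `[[`, numeric(1), "thickness")
  hu_layers <- vapply(spec$layers, `[[`, numeric(1), "hu")
  # snap thicknesses and the top interface to voxel boundaries along z;
  # voxel centers lie at k * dz (origin at voxel (0,0,0)), boundaries at
  # (k +/- 0.5) * dz
  dz <- sp[3]
  th_snap <- pmax(round(th / dz), 1L) * dz
  total <- sum(th_snap)
  lz <- nvox[3] * dz
  z_top <- (floor((lz - 3) / dz) + 0.5) * dz  # ~3 mm air above the slab
  z_bottom <- z_top - total
  if (z_bottom < 0.5 * dz)
    stop("generate_slab: layers thicker than the volume allows")
  zc <- (seq_len(nvox[3]) - 1L) * dz
  hu_col <- rep(-1000, nvox[3])
  interfaces <- z_top - cumsum(c(0, th_snap))
  for (l in seq_along(th_snap)) {
    in_layer <- zc < interfaces[l] & zc > interfaces[l + 1]
    hu_col[in_layer] <- hu_layers[l]
  }
  data <- array(rep(hu_col, each = nvox[1] * nvox[2]), dim = nvox)

  truth_cells <- NULL
  with_phantom_rng(spec$seed, {
    ac <- spec$air_cell_params
    if (!is.null(ac) && ac$fraction > 0) {
      l <- ac$layer
      if (l > length(th_snap)) stop("generate_slab: air-cell layer index out of range")
      z1 <- interfaces[l]; z0 <- interfaces[l + 1]
      r <- ac$radius
      v_sphere <- 4 / 3 * pi * r^3
      lam <- -log(1 - ac$fraction) / v_sphere
      # Poisson centers in the r-dilated layer box so coverage inside the
      # layer is uniform (Boolean germ-grain model)
      box <- c(spec$dim_mm[1] + 2 * r, spec$dim_mm[2] + 2 * r, (z1 - z0) + 2 * r)
      ncell <- round(lam * prod(box))
      cx <- runif(ncell, -r, spec$dim_mm[1] + r)
      cy <- runif(ncell, -r, spec$dim_mm[2] + r)
      czp <- runif(ncell, z0 - r, z1 + r)
      xs <- (seq_len(nvox[1]) - 1L) * sp[1]
      ys <- (seq_len(nvox[2]) - 1L) * sp[2]
      in_layer_k <- which(zc < z1 & zc > z0)
      for (s in seq_len(ncell)) {
        ir <- which(abs(xs - cx[s]) <= r)
        jr <- which(abs(ys - cy[s]) <= r)
        kr <- in_layer_k[abs(zc[in_layer_k] - czp[s]) <= r]
        if (!length(ir) || !length(jr) || !length(kr)) next
        dx2 <- (xs[ir] - cx[s])^2
        dy2 <- (ys[jr] - cy[s])^2
        dz2 <- (zc[kr] - czp[s])^2
        d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
        hit <- which(d2 <= r^2, arr.ind = TRUE)
        if (nrow(hit))
          data[cbind(ir[hit[, 1]], jr[hit[, 2]], kr[hit[, 3]])] <- ac$hu
      }
      truth_cells <- list(n = ncell, radius = r, fraction = ac$fraction,
                          layer = l)
    }
    if (spec$noise_sd > 0)
      data <- data + array(rnorm(length(data), sd = spec$noise_sd), dim = nvox)
  })

  volume <- ct_volume(data, spacing = sp)
  profile_fun <- function(depths) {
    z <- z_top - depths
    hu <- rep(-1000, length(depths))
    for (l in seq_along(th_snap))
      hu[z <= interfaces[l] & z > interfaces[l + 1]] <- hu_layers[l]
    hu[depths < 0] <- -1000
    hu
  }
  # analytic indices for an ideal perpendicular probe, default parameters
  p <- .tb_defaults
  d_tb <- min(total, p$d_max)
  depths <- seq(0, d_tb + 1e-9, by = p$delta_d)
  depths <- depths[depths <= d_tb + 1e-9]
  prof <- synthetic_profile(profile_fun(depths), p$delta_d, d_tb)
  cort <- cortical_density(prof$samples, p$delta_d, p$onset_hu,
                           p$cortical_window)
  sisi_t <- setNames(vapply(p$d_min, function(dm) sisi(prof, dm, p$onset_hu),
                            numeric(1)), paste0("sisi_", p$d_min))
  truth <- list(z_top = z_top, z_bottom = z_bottom, interfaces = interfaces,
                layer_hu = hu_layers, layer_thickness = th_snap,
                thickness = total, profile_fun = profile_fun,
                d_tb = d_tb, cortical_hu = cort$cortical_hu,
                sisi = sisi_t, codi = codi(prof, calibration),
                air_cells = truth_cells)
  structure(list(volume = volume, truth = truth, spec = spec),
            class = "slab_phantom")
}

#' Frame and landmarks for a slab phantom
#'
#' Places the retroauricular frame so that probes travel along -z onto the
#' slab's top surface and a grid window in frame (x, y) is centered on the
#' slab laterally. Also returns the implied landmark triple (Henle's spine
#' and two zygomatic points) in scanner coordinates, usable to exercise the
#' full landmark-driven pipeline.
#'
#' @param phantom A `slab_phantom`.
#' @param grid_window Frame-coordinate window `c(xmin, xmax, ymin, ymax)` to
#'   center, default the standard ROI `c(4, 39, -10, 25)`.
#' @param clearance Lateral stand-off of the frame origin above the slab
#'   surface (mm).
#' @return List with `frame` (a `retro_frame`) and `landmarks`
#'   (`henle`, `zyg_a`, `zyg_b`, plus `axial_normal` and `posterior_hint`).
#' @export
slab_frame <- function(phantom, grid_window = c(4, 39, -10, 25),
                       clearance = 5) {
  stopifnot(inherits(phantom, "slab_phantom"))
  ext <- phantom$spec$dim_mm
  ox <- ext[1] / 2 - (grid_window[1] + grid_window[2]) / 2
  oy <- ext[2] / 2 - (grid_window[3] + grid_window[4]) / 2
  henle <- c(ox, oy, phantom$truth$z_top + clearance)
  landmarks <- list(henle = henle,
                    zyg_a = henle + c(-10, 0, 0), zyg_b = henle + c(-20, 0, 0),
                    axial_normal = c(0, 1, 0), posterior_hint = c(1, 0, 0))
  frame <- build_frame(landmarks$henle, landmarks$zyg_a, landmarks$zyg_b,
                       axial_normal = landmarks$axial_normal, side = "right",
                       posterior_hint = landmarks$posterior_hint)
  list(frame = frame, landmarks = landmarks)
}

#' Generate the six-insert density calibration phantom
#'
#' Six cylindrical inserts (axis along z) at hydroxyapatite densities 0
#' (water), 100, 200, 400, 600 and 800 mg HA/cm^3, embedded in a water-
#' equivalent body (0 HU); the insert radiodensity is
#' `slope * density + intercept` plus optional Gaussian noise. The returned
#' insert table holds the measured per-insert mean HU, as a real phantom
#' evaluation would.
#'
#' @param spec A `phantom_spec` of kind `"calibration"`.
#' @param slope True HU per (mg HA/cm^3), default 1.32.
#' @param intercept True HU at zero density, default 0.
#' @param densities Insert densities (mg HA/cm^3).
#' @param insert_radius Cylinder radius (mm).
#' @return List (class `calibration_phantom`) with `volume`, `insert_table`
#'   (`density_mg_ha_cm3`, `mean_hu`, `n_voxels`), and `truth`
#'   (`slope`, `intercept`).
#' @export
generate_calibration <- function(spec = phantom_spec("calibration"),
                                 slope = 1.32, intercept = 0,
                                 densities = c(0, 100, 200, 400, 600, 800),
                                 insert_radius = 3.5) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "calibration",
            slope > 0)
  sp <- spec$spacing
  nvox <- pmax(round(spec$dim_mm / sp), 2L)
  xs <- (seq_len(nvox[1]) - 1L) * sp[1]
  ys <- (seq_len(nvox[2]) - 1L) * sp[2]
  data <- array(0, dim = nvox)  # water-equivalent body
  k_in <- which((seq_len(nvox[3]) - 1L) * sp[3] >= 2 &
                (seq_len(nvox[3]) - 1L) * sp[3] <= spec$dim_mm[3] - 2)
  centers_x <- spec$dim_mm[1] * (seq_along(densities) - 0.5) / length(densities)
  center_y <- spec$dim_mm[2] / 2
  masks <- vector("list", length(densities))
  for (m in seq_along(densities)) {
    in_circ <- outer((xs - centers_x[m])^2, (ys - center_y)^2, "+") <=
      insert_radius^2
    ij <- which(in_circ, arr.ind = TRUE)
    idx <- cbind(ij[rep(seq_len(nrow(ij)), length(k_in)), , drop = FALSE],
                 rep(k_in, each = nrow(ij)))
    data[idx] <- slope * densities[m] + intercept
    masks[[m]] <- idx
  }
  with_phantom_rng(spec$seed, {
    if (spec$noise_sd > 0)
      data <- data + array(rnorm(length(data), sd = spec$noise_sd),
                           dim = nvox)
  })
  volume <- ct_volume(data, spacing = sp)
  insert_table <- data.frame(
    density_mg_ha_cm3 = densities,
    mean_hu = vapply(masks, function(m) mean(data[m]), numeric(1)),
    n_voxels = vapply(masks, nrow, integer(1)))
  structure(list(volume = volume, insert_table = insert_table,
                 truth = list(slope = slope, intercept = intercept),
                 spec = spec),
            class = "calibration_phantom")
}
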