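# End-to-end analysis: segmentation -> mesh -> frame -> grid -> probing ->
# indices, returning the per-probe table together with the intermediate
# objects.

#' Probe the retroauricular temporal bone
#'
#' Runs the full morphometry pipeline on a calibrated CT volume: threshold
#' segmentation at 620 HU with 300-voxel island removal, smoothed
#' outer-surface mesh extraction, retroauricular frame construction from the
#' landmark triple, 8 x 8 probe grid generation, trajectory sampling, and
#' per-probe thickness, cortical density, SISI and CODI.
#'
#' @param volume A [ct_volume] in HU.
#' @param landmarks Named list with `henle`, `zyg_a`, `zyg_b` (scanner mm);
#'   optional `axial_normal`, `posterior_hint`.
#' @param calibration A `calibration_model`, or `NULL` to fall back to the
#'   published 1.32 slope (a message notes the uncalibrated fallback).
#' @param side `"right"` or `"left"` ear.
#' @param subject Subject identifier for the result table.
#' @param params Named list overriding entries of [tb_defaults()].
#' @return A `tb_probe_result`: list with `table` (the `probe_table`),
#'   `mesh`, `frame`, `grid`, `calibration`, `params`.
#' @export
probe_temporal_bone <- function(volume, landmarks, calibration = NULL,
                                side = "right", subject = "subject1",
                                params = list()) {
  p <- utils::modifyList(.tb_defaults, params)
  if (is.null(calibration)) {
    message("probe_temporal_bone: no calibration supplied; using the ",
            "published slope 1.32 HU per (mg HA/cm^3) - conversions are ",
            "approximate for this scanner")
    calibration <- default_calibration()
  }
  label <- label_bone(volume, threshold_hu = p$threshold_hu)
  label <- remove_islands(label, min_voxels = p$min_island_voxels)
  if (!any(label$mask))
    stop("probe_temporal_bone: no bone voxels after segmentation")
  mesh <- build_mesh(label, smoothing_mm = p$smoothing_mm)
  frame <- build_frame(landmarks$henle, landmarks$zyg_a, landmarks$zyg_b,
                       axial_normal = if (is.null(landmarks$axial_normal))
                         c(0, 0, 1) else landmarks$axial_normal,
                       side = side,
                       posterior_hint = if (is.null(landmarks$posterior_hint))
                         c(0, -1, 0) else landmarks$posterior_hint)
  grid <- make_grid(frame, nx = p$grid_nx, ny = p$grid_ny,
                    spacing = p$grid_spacing, corner = p$grid_corner)
  table <- probe_table(volume, mesh, grid, calibration = calibration,
                       subject = subject, d_min = p$d_min,
                       delta_d = p$delta_d, d_max = p$d_max,
                       onset_hu = p$onset_hu, window_mm = p$cortical_window)
  structure(list(table = table, mesh = mesh, frame = frame, grid = grid,
                 calibration = calibration, params = p, subject = subject),
            class = "tb_probe_result")
}

#' @export
print.tb_probe_result <- function(x, ...) {
  t <- x$table
  ok <- t$status == "ok"
  cat("Temporal bone probe run (", x$subject, "): ", sum(ok), " of ",
      nrow(t), " probes intersect bone\n", sep = "")
  if (any(ok)) {
    cat("  d_TB     :", paste(signif(range(t$d_tb_mm[ok]), 4),
                              collapse = " .. "), "mm\n")
    cat("  cortical :", paste(signif(range(t$cortical_hu[ok], na.rm = TRUE), 5),
                              collapse = " .. "), "HU\n")
    cat("  CODI     :", paste(signif(range(t$codi[ok]), 4),
                              collapse = " .. "), "mg HA/mm^2\n")
  }
  invisible(x)
}

#' @export
summary.tb_probe_result <- function(object, ...) {
  t <- object$table
  ok <- t$status == "ok"
  sisi_cols <- grep("^sisi_", names(t), value = TRUE)
  out <- data.frame(
    measure = c("d_tb_mm", "cortical_hu", "cortical_bmd", sisi_cols, "codi"))
  out$mean <- vapply(out$measure, function(m) mean(t[[m]][ok], na.rm = TRUE),
                     numeric(1))
  out$sd <- vapply(out$measure, function(m) sd(t[[m]][ok], na.rm = TRUE),
                   numeric(1))
  out$n <- vapply(out$measure, function(m) sum(!is.na(t[[m]][ok])),
                  integer(1))
  out
}

#' @export
plot.tb_probe_result <- function(x, measure = "d_tb_mm", ...) {
  plot(aggregate_grid(list(x$table), measure), ...)
}
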