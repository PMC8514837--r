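# Preoperative planning indices derived from a probe profile.
#
# SISI (Screw Implantation Safety Index): for a screw of length d_min, the
# percentage of trajectory samples within d_min that are dense bone
# (>= 1000 HU); 0 when the bone is thinner than the screw (d_TB <= d_min).
#
# CODI (Column Density Index): the line integral of calibrated bone mineral
# density along the trajectory over the full bone thickness, i.e. the column
# mass per unit area (mg HA/mm^2).

#' Screw Implantation Safety Index
#'
#' If the bone is not thicker than the screw-length threshold
#' (`d_tb <= d_min`) the index is 0. Otherwise it is `100 * N_S / N`, where
#' `N` is the total number of samples at depth `<= d_min` (air and soft
#' tissue included) and `N_S` the number of those with radiodensity at least
#' `dense_hu` (inclusive).
#'
#' @param profile A `probe_profile` (see [probe_profile()],
#'   [synthetic_profile()]).
#' @param d_min Screw-length threshold in mm (> 0).
#' @param dense_hu Dense-bone threshold, default 1000 HU.
#' @return SISI in percent (0..100).
#' @export
sisi <- function(profile, d_min, dense_hu = 1000) {
  stopifnot(inherits(profile, "probe_profile"), d_min > 0)
  if (profile$status != "ok")
    stop("sisi: profile status is '", profile$status, "'")
  if (profile$d_tb <= d_min) return(0)
  depths <- (seq_along(profile$samples) - 1L) * profile$delta_d
  within <- depths <= d_min + 1e-9
  n <- sum(within)
  if (n == 0L) return(0)
  100 * sum(profile$samples[within] >= dense_hu) / n
}

#' Column Density Index
#'
#' Riemann sum of the calibrated bone mineral density along the trajectory:
#' each HU sample is converted to mg HA/cm^3 via the calibration model,
#' divided by 1000 to mg HA/mm^3, multiplied by the sampling interval
#' `delta_d` (mm) and summed, yielding mg HA/mm^2. By default the sum runs
#' over the full temporal bone thickness (all samples of the profile, which
#' is truncated at `d_TB`, itself capped at 18 mm); `bound = "d_min"`
#' restricts it to samples within `d_min`.
#'
#' @param profile A `probe_profile`.
#' @param model A `calibration_model`.
#' @param bound `"d_tb"` (default) or `"d_min"`.
#' @param d_min Threshold in mm, required when `bound = "d_min"`.
#' @return CODI in mg HA/mm^2 (non-negative).
#' @export
codi <- function(profile, model, bound = c("d_tb", "d_min"), d_min = NULL) {
  bound <- match.arg(bound)
  stopifnot(inherits(profile, "probe_profile"),
            inherits(model, "calibration_model"))
  if (profile$status != "ok")
    stop("codi: profile status is '", profile$status, "'")
  samples <- profile$samples
  depths <- (seq_along(samples) - 1L) * profile$delta_d
  keep <- depths <= min(profile$d_tb, 18) + 1e-9
  if (bound == "d_min") {
    if (is.null(d_min)) stop("codi: d_min required when bound = 'd_min'")
    keep <- keep & depths <= d_min + 1e-9
  }
  bmd_mm3 <- hu_to_bmd(model, samples[keep]) / 1000  # mg HA/mm^3
  sum(bmd_mm3 * profile$delta_d)
}

#' All indices for a probe profile
#'
#' @param profile A `probe_profile`.
#' @param model A `calibration_model`.
#' @param d_min Numeric vector of screw-length thresholds (mm).
#' @param dense_hu Dense-bone threshold (HU).
#' @return List with `sisi_by_dmin` (named, percent), `codi`
#'   (mg HA/mm^2), and per-threshold counts `n_samples_dmin` (N) and
#'   `n_dense` (N_S).
#' @export
index_result <- function(profile, model, d_min = c(4, 5), dense_hu = 1000) {
  depths <- (seq_along(profile$samples) - 1L) * profile$delta_d
  counts <- lapply(d_min, function(dm) {
    within <- depths <= dm + 1e-9
    list(n = sum(within),
         n_dense = sum(profile$samples[within] >= dense_hu))
  })
  list(sisi_by_dmin = setNames(vapply(d_min, function(dm)
         sisi(profile, dm, dense_hu), numeric(1)), paste0("sisi_", d_min)),
       codi = codi(profile, model),
       n_samples_dmin = setNames(vapply(counts, `[[`, integer(1), "n"),
                                 paste0("n_", d_min)),
       n_dense = setNames(vapply(counts, `[[`, integer(1), "n_dense"),
                          paste0("ns_", d_min)))
}
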