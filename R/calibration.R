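# HU <-> bone-mineral-density calibration from a density phantom.
# The phantom provides inserts of known hydroxyapatite concentration
# (mg HA/cm^3); the relation between measured radiodensity and density is
# linear over the clinical range, so an ordinary least-squares line
# HU = slope * density + intercept is fitted and inverted for conversion.

#' Fit the HU/bone-mineral-density calibration line
#'
#' Ordinary least-squares fit of `HU = slope * density + intercept` to the
#' measured mean radiodensity of the phantom inserts.
#'
#' @param insert_table Data frame or matrix with two columns: known density
#'   (mg HA/cm^3, non-negative) and measured mean HU. Column names
#'   `density_mg_ha_cm3` and `mean_hu` are recognized; otherwise the first
#'   two columns are used in that order.
#' @return A `calibration_model` with fields `slope` (HU per mg HA/cm^3),
#'   `intercept` (HU at zero density), `insert_table` and `residuals`.
#' @export
fit_calibration <- function(insert_table) {
  tab <- as.data.frame(insert_table)
  if (all(c("density_mg_ha_cm3", "mean_hu") %in% names(tab))) {
    density <- tab$density_mg_ha_cm3
    hu <- tab$mean_hu
  } else {
    if (ncol(tab) < 2L)
      stop("fit_calibration: insert table needs (density, mean HU) columns")
    density <- tab[[1]]
    hu <- tab[[2]]
  }
  density <- as.numeric(density)
  hu <- as.numeric(hu)
  if (length(density) < 2L || length(unique(density)) < 2L)
    stop("fit_calibration: need at least two distinct density values ",
         "(degenerate fit)")
  if (any(density < 0))
    stop("fit_calibration: densities must be non-negative")
  fit <- lm(hu ~ density)
  calibration_model(slope = unname(coef(fit)[2]),
                    intercept = unname(coef(fit)[1]),
                    insert_table = data.frame(density_mg_ha_cm3 = density,
                                              mean_hu = hu),
                    residuals = unname(residuals(fit)))
}

#' Construct a calibration model directly
#'
#' @param slope HU per (mg HA/cm^3); must be positive.
#' @param intercept HU at zero density.
#' @param insert_table Optional insert table used for the fit.
#' @param residuals Optional fit residuals (HU).
#' @return A `calibration_model`.
#' @export
calibration_model <- function(slope, intercept = 0, insert_table = NULL,
                              residuals = NULL) {
  if (!is.finite(slope) || slope <= 0)
    stop("calibration_model: slope must be positive")
  structure(list(slope = slope, intercept = intercept,
                 insert_table = insert_table, residuals = residuals),
            class = "calibration_model")
}

#' Published default calibration
#'
#' The scaling factor between radiodensity and bone mineral density for the
#' high-resolution temporal-bone protocol is 1.32 HU per (mg HA/cm^3) with
#' zero intercept. Use only when no phantom table is available for the
#' scanner at hand; conversions are then approximate.
#'
#' @return A `calibration_model` with slope 1.32 and intercept 0.
#' @export
default_calibration <- function() calibration_model(1.32, 0)

#' @export
print.calibration_model <- function(x, ...) {
  cat("HU/BMD calibration: HU =", signif(x$slope, 6), "* density +",
      signif(x$intercept, 6), "\n")
  if (!is.null(x$insert_table))
    cat("  fitted on", nrow(x$insert_table), "inserts; residual SD",
        signif(sd(x$residuals), 4), "HU\n")
  invisible(x)
}

#' Convert radiodensity to calibrated bone mineral density
#'
#' Negative HU values are set to 0 before conversion so that only positive
#' calibrated densities are produced; any density still negative after the
#' intercept shift is floored at 0. Vectorized over profiles.
#'
#' @param model A `calibration_model`.
#' @param hu Radiodensity values (HU).
#' @return Bone mineral density values (mg HA/cm^3), non-negative.
#' @export
hu_to_bmd <- function(model, hu) {
  stopifnot(inherits(model, "calibration_model"))
  pmax((pmax(hu, 0) - model$intercept) / model$slope, 0)
}

#' Read a calibration insert table from CSV
#'
#' Expects columns `density_mg_ha_cm3` and `mean_hu` (or two unnamed columns
#' in that order).
#'
#' @param path CSV path.
#' @return Data frame suitable for [fit_calibration()].
#' @export
read_calibration_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON path.
#' @return `write_calibration_json` returns the path invisibly;
#'   `read_calibration_json` returns the model.
#' @export
write_calibration_json <- function(model, path) {
  jsonlite::write_json(list(slope = model$slope, intercept = model$intercept,
                            insert_table = model$insert_table),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(obj$slope, obj$intercept,
                    insert_table = obj$insert_table)
}
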