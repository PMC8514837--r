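# Reading and writing CT volumes (NIfTI via RNifti, DICOM series via the
# internal codec in dicom.R) and per-probe result tables. All volumes are
# normalized on read to the canonical RAS-like physical convention.

#' Read a CT volume
#'
#' Reads a NIfTI-1 file (`.nii`/`.nii.gz`) or a DICOM series (a directory of
#' single-frame CT slices) and normalizes the geometry into the package's
#' canonical convention: physical millimetre coordinates, RAS-like axes,
#' 0-based voxel indices addressing voxel centers. Stored values are rescaled
#' to Hounsfield units using the format's slope/intercept metadata.
#'
#' @param path Path to a NIfTI file or a DICOM series directory.
#' @param format `"auto"` (default; directories are treated as DICOM series),
#'   `"nifti"`, or `"dicom"`.
#' @return A [ct_volume].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (!file.exists(path)) stop("read_volume: path does not exist: ", path)
  if (format == "dicom") return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (length(dim(img)) != 3L)
    stop("read_volume: only 3D NIfTI volumes are supported (dim: ",
         paste(dim(img), collapse = "x"), ")")
  if (hdr$qform_code > 0L || hdr$sform_code > 0L) {
    # reorient data to the closest RAS layout, then decompose the affine
    RNifti::orientation(img) <- "RAS"
    aff <- RNifti::xform(img)
    axes <- aff[1:3, 1:3]
    spacing <- sqrt(colSums(axes^2))
    if (any(spacing <= 0) || !all(is.finite(spacing)))
      stop("read_volume: degenerate affine (zero-length axis) in sform/qform")
    axes <- sweep(axes, 2L, spacing, "/")
    if (max(abs(crossprod(axes) - diag(3))) > 1e-4)
      stop("read_volume: sheared (non-orthonormal) sform/qform is not supported")
    origin <- aff[1:3, 4]
  } else {
    spacing <- RNifti::pixdim(img)[1:3]
    if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
    axes <- diag(3)
    origin <- c(0, 0, 0)
  }
  data <- array(as.numeric(img), dim = dim(img))
  slope <- hdr$scl_slope
  inter <- hdr$scl_inter
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    data <- data * slope + inter
  ct_volume(data, spacing = spacing, origin = origin, axes = axes)
}

#' Write a CT volume to NIfTI
#'
#' @param volume A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$data
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr)
  aff <- rbind(cbind(volume$axes %*% diag(volume$spacing), volume$origin),
               c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

.results_fixed_cols <- c("subject", "grid_x", "grid_y", "d_tb_mm",
                         "cortical_hu", "cortical_bmd")

#' Write a per-probe result table
#'
#' Writes one CSV row per (subject, grid_x, grid_y) with bone thickness,
#' cortical density in HU and mg HA/cm^3, SISI per screw-length threshold,
#' CODI and probe status, in a stable column order. Probes without a mesh
#' intersection keep their row; their measurement fields are written empty.
#'
#' @param table Data frame as produced by [probe_table()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("write_results: 'table' must be a non-empty data frame")
  sisi_cols <- sort(grep("^sisi_", names(table), value = TRUE))
  cols <- c(.results_fixed_cols, sisi_cols, "codi", "status")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("write_results: table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  ok <- tryCatch({
    write.csv(table[, cols], path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_results: cannot write to ", path)
  invisible(path)
}

#' Read a per-probe result table written by [write_results()]
#'
#' @param path CSV path.
#' @return Data frame with empty fields restored as `NA`.
#' @export
read_results <- function(path) {
  read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
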