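# CT volume container and geometry. All downstream computation happens in
# physical millimetre coordinates in a canonical right-anterior-superior
# (RAS-like) convention; voxel indices are 0-based and refer to voxel centers.

#' CT volume in Hounsfield units
#'
#' Container for a 3D radiodensity field with its geometry: per-axis voxel
#' spacing, the physical position of voxel (0,0,0), and direction cosines
#' mapping voxel indices to physical space. The physical position of voxel
#' index (i,j,k) (0-based, voxel center) is
#' `origin + axes %*% (i*spacing[1], j*spacing[2], k*spacing[3])`.
#'
#' @param data 3D numeric array of radiodensity (HU).
#' @param spacing Length-3 positive numeric, voxel size in mm.
#' @param origin Length-3 numeric, physical position (mm) of voxel (0,0,0).
#' @param axes 3x3 orthonormal right-handed direction-cosine matrix (columns
#'   are the physical directions of the i, j, k index axes).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0), axes = diag(3)) {
  if (length(dim(data)) != 3L) stop("ct_volume: 'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: 'spacing' must be three strictly positive values")
  if (length(origin) != 3L) stop("ct_volume: 'origin' must have length 3")
  if (!all(dim(axes) == c(3L, 3L)))
    stop("ct_volume: 'axes' must be a 3x3 matrix")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop("ct_volume: 'axes' must be orthonormal")
  if (det(axes) < 0)
    stop("ct_volume: 'axes' must form a right-handed basis")
  structure(list(data = data, spacing = spacing, origin = origin, axes = axes),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("CT volume:", paste(d, collapse = " x "), "voxels\n")
  cat("  spacing :", paste(signif(x$spacing, 6), collapse = " x "), "mm\n")
  cat("  origin  :", paste(signif(x$origin, 6), collapse = ", "), "mm\n")
  cat("  HU range:", paste(signif(range(x$data), 6), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Map voxel indices to physical coordinates
#'
#' @param volume A [ct_volume].
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed (continuous index space).
#' @return n x 3 matrix of physical positions (mm).
#' @export
voxel_to_physical <- function(volume, ijk) {
  ijk <- rbind_points(ijk)
  p <- (ijk * rep(volume$spacing, each = nrow(ijk))) %*% t(volume$axes)
  sweep(p, 2L, volume$origin, "+")
}

#' Map physical coordinates to continuous voxel indices
#'
#' @param volume A [ct_volume].
#' @param points n x 3 matrix (or length-3 vector) of physical positions (mm).
#' @return n x 3 matrix of 0-based continuous voxel indices.
#' @export
physical_to_voxel <- function(volume, points) {
  points <- rbind_points(points)
  d <- sweep(points, 2L, volume$origin, "-") %*% volume$axes
  d / rep(volume$spacing, each = nrow(d))
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1L)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must have 3 columns")
  p
}

#' Physical bounding box of a volume
#'
#' The box spanned by the voxel extents (voxel centers plus half a voxel on
#' each side), as an axis-aligned range in physical space.
#'
#' @param volume A [ct_volume].
#' @return 2 x 3 matrix: rows are min and max, columns x/y/z (mm).
#' @export
physical_bbox <- function(volume) {
  d <- dim(volume$data)
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5),
                                   c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  p <- voxel_to_physical(volume, corners)
  rbind(min = apply(p, 2L, min), max = apply(p, 2L, max))
}

#' Interpolate radiodensity at physical positions
#'
#' Trilinear (default) or nearest-voxel interpolation of the HU field.
#' Positions outside the voxel extent return `NA`.
#'
#' @param volume A [ct_volume].
#' @param points n x 3 matrix of physical positions (mm).
#' @param method `"trilinear"` or `"nearest"`.
#' @return Numeric vector of interpolated HU values.
#' @export
interp_hu <- function(volume, points, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  idx <- physical_to_voxel(volume, points)
  d <- dim(volume$data)
  out <- rep(NA_real_, nrow(idx))
  inside <- idx[, 1] >= -0.5 & idx[, 1] <= d[1] - 0.5 &
            idx[, 2] >= -0.5 & idx[, 2] <= d[2] - 0.5 &
            idx[, 3] >= -0.5 & idx[, 3] <= d[3] - 0.5
  if (!any(inside)) return(out)
  ix <- idx[inside, , drop = FALSE]
  if (method == "nearest") {
    ii <- pmin(pmax(round(ix), 0), rep(d - 1L, each = nrow(ix)))
    out[inside] <- volume$data[ii + 1L]
    return(out)
  }
  # trilinear with edge clamping in the half-voxel border
  f <- pmin(pmax(ix, 0), rep(d - 1L, each = nrow(ix)))
  i0 <- floor(f)
  i0 <- pmin(i0, rep(d - 2L, each = nrow(i0)))
  i0 <- pmax(i0, 0)
  w <- f - i0
  acc <- numeric(nrow(f))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    keep <- wt > 0
    if (any(keep)) {
      sub <- cbind(i0[keep, 1] + dx, i0[keep, 2] + dy, i0[keep, 3] + dz) + 1L
      acc[keep] <- acc[keep] + wt[keep] * volume$data[sub]
    }
  }
  out[inside] <- acc
  out
}
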