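# Bone segmentation and outer-surface mesh extraction: threshold labeling
# at the compact-bone threshold, removal of small disconnected islands
# (speckle and isolated air-cell walls), isosurface extraction and low-pass
# mesh smoothing. The threshold comparison is inclusive (HU >= threshold) so
# the boundary case is deterministic.

#' Label bone voxels by thresholding
#'
#' @param volume A [ct_volume].
#' @param threshold_hu Labeling threshold; voxels with HU >= this value are
#'   labeled bone. Default 620 HU (compact bone).
#' @return A `bone_label`: logical mask aligned with the volume plus the
#'   volume geometry and the parameters applied.
#' @export
label_bone <- function(volume, threshold_hu = 620) {
  stopifnot(inherits(volume, "ct_volume"))
  mask <- volume$data >= threshold_hu
  structure(list(mask = mask, threshold_hu = threshold_hu,
                 min_island_voxels = NA_integer_,
                 spacing = volume$spacing, origin = volume$origin,
                 axes = volume$axes),
            class = "bone_label")
}

#' @export
print.bone_label <- function(x, ...) {
  cat("Bone label:", sum(x$mask), "of", length(x$mask),
      "voxels >=", x$threshold_hu, "HU\n")
  if (!is.na(x$min_island_voxels))
    cat("  islands <", x$min_island_voxels, "voxels removed\n")
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  labels <- label_components_cpp(as.logical(mask), dim(mask),
                                 as.integer(connectivity))
  array(labels, dim = dim(mask))
}

#' Remove small disconnected islands from a bone label
#'
#' Connected components (26-connectivity by default) with fewer than
#' `min_voxels` voxels are deleted; larger components are retained unchanged.
#' Operates on the foreground only.
#'
#' @param label A `bone_label`.
#' @param min_voxels Island-removal cutoff; components with fewer voxels
#'   ("less than 300" by default) are removed.
#' @param connectivity 26 (default) or 6.
#' @return The filtered `bone_label`.
#' @export
remove_islands <- function(label, min_voxels = 300, connectivity = 26) {
  stopifnot(inherits(label, "bone_label"))
  comp <- label_components(label$mask, connectivity)
  n <- max(comp)
  if (n > 0L) {
    sizes <- tabulate(comp[comp > 0L], nbins = n)
    keep <- which(sizes >= min_voxels)
    label$mask <- array(comp %in% keep & comp > 0L, dim = dim(comp))
  }
  label$min_island_voxels <- min_voxels
  label
}

#' Triangulated bone surface mesh
#'
#' Constructs a `bone_mesh` from raw arrays, computing per-triangle unit
#' outward normals and areas from the vertex winding.
#'
#' @param vertices n x 3 matrix of physical vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices; counter-
#'   clockwise winding seen from outside.
#' @return A `bone_mesh` with fields `vertices`, `faces`, `normals`, `areas`.
#' @export
bone_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("bone_mesh: vertices and faces must have 3 columns")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("bone_mesh: face indices out of range")
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  if (any(len == 0)) stop("bone_mesh: degenerate (zero-area) triangle")
  structure(list(vertices = vertices, faces = faces,
                 normals = nrm / len, areas = len / 2),
            class = "bone_mesh")
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat("Bone mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "triangles, area", signif(sum(x$areas), 6), "mm^2\n")
  invisible(x)
}

#' Total surface area of a mesh
#' @param mesh A `bone_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(mesh$areas)

#' Extract the raw isosurface of a bone label
#'
#' Marching-tetrahedra isosurface of the binary mask (iso level between
#' foreground and background, i.e. midway between boundary voxel centers),
#' in physical coordinates, without smoothing. The mask is padded so the
#' surface is closed at the volume boundary.
#'
#' @param label A `bone_label`.
#' @return A `bone_mesh`.
#' @export
extract_isosurface <- function(label) {
  stopifnot(inherits(label, "bone_label"))
  if (!any(label$mask)) stop("extract_isosurface: empty label")
  d <- dim(label$mask)
  padded <- array(FALSE, dim = d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- label$mask
  res <- mt_isosurface_cpp(padded, dim(padded))
  idx <- res$vertices - 1  # undo padding offset; 0-based voxel index space
  p <- (idx * rep(label$spacing, each = nrow(idx))) %*% t(label$axes)
  p <- sweep(p, 2L, label$origin, "+")
  bone_mesh(p, res$faces + 1L)
}

#' Build the smoothed outer bone surface mesh
#'
#' Isosurface extraction followed by Taubin (lambda|mu) low-pass smoothing,
#' a non-shrinking iterative filter. The number of smoothing iterations is
#' chosen so that the filter's spatial scale matches a Gaussian kernel of
#' width `smoothing_mm` (sigma = smoothing_mm / 2); `smoothing_mm = 0`
#' returns the raw isosurface vertices unchanged. Outward normal orientation
#' is verified against the mask interior.
#'
#' @param label A `bone_label` with at least one foreground voxel.
#' @param smoothing_mm Spatial smoothing scale in mm (default 4).
#' @param lambda,mu Taubin filter factors.
#' @param max_iterations Upper bound on smoothing iterations.
#' @return A `bone_mesh`.
#' @export
build_mesh <- function(label, smoothing_mm = 4, lambda = 0.5, mu = -0.53,
                       max_iterations = 500L) {
  mesh <- extract_isosurface(label)
  if (smoothing_mm > 0) {
    # mean edge length from the first edge of each triangle
    e <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] -
         mesh$vertices[mesh$faces[, 1], , drop = FALSE]
    h2 <- mean(rowSums(e^2))
    iters <- min(max_iterations,
                 max(1L, as.integer(round((smoothing_mm / 2)^2 / (lambda * h2)))))
    v <- taubin_smooth_cpp(mesh$vertices, mesh$faces - 1L, iters, lambda, mu)
    mesh <- bone_mesh(v, mesh$faces)
  }
  # orientation check: just inside the surface (against the outward normal)
  # the mask should be foreground
  n_check <- min(200L, nrow(mesh$faces))
  sel <- unique(as.integer(seq(1L, nrow(mesh$faces), length.out = n_check)))
  centroid <- (mesh$vertices[mesh$faces[sel, 1], , drop = FALSE] +
               mesh$vertices[mesh$faces[sel, 2], , drop = FALSE] +
               mesh$vertices[mesh$faces[sel, 3], , drop = FALSE]) / 3
  probe <- centroid - mesh$normals[sel, , drop = FALSE] * min(label$spacing)
  idx <- round(sweep(probe, 2L, label$origin, "-") %*% label$axes /
                 rep(label$spacing, each = nrow(probe)))
  d <- dim(label$mask)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] & idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  inside <- rep(FALSE, nrow(idx))
  if (any(ok)) inside[ok] <- label$mask[idx[ok, , drop = FALSE] + 1L]
  if (mean(inside) < 0.5) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
    mesh$normals <- -mesh$normals
  }
  mesh
}

#' Export a mesh as ASCII PLY or STL
#'
#' @param mesh A `bone_mesh`.
#' @param path Output path; format follows the `.ply`/`.stl` extension
#'   unless `format` is given.
#' @param format `"ply"` or `"stl"` (default: from extension).
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("ply", "stl"))
    stop("write_mesh: format must be 'ply' or 'stl'")
  if (format == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(mesh$vertices)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(mesh$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 9), 1L,
                     paste, collapse = " "), con)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid bone", con)
    fmt <- function(m) apply(format(m, trim = TRUE, digits = 9), 1L,
                             paste, collapse = " ")
    v1 <- fmt(mesh$vertices[mesh$faces[, 1], , drop = FALSE])
    v2 <- fmt(mesh$vertices[mesh$faces[, 2], , drop = FALSE])
    v3 <- fmt(mesh$vertices[mesh$faces[, 3], , drop = FALSE])
    nn <- fmt(mesh$normals)
    writeLines(paste0("facet normal ", nn, "\n outer loop\n  vertex ", v1,
                      "\n  vertex ", v2, "\n  vertex ", v3,
                      "\n endloop\nendfacet"), con)
    writeLines("endsolid bone", con)
  }
  invisible(path)
}

#' Export a bone label as a NIfTI mask
#'
#' @param label A `bone_label`.
#' @param path Output path (`.nii`/`.nii.gz`).
#' @return The path, invisibly.
#' @export
write_label_nifti <- function(label, path) {
  vol <- ct_volume(array(as.integer(label$mask), dim = dim(label$mask)),
                   spacing = label$spacing, origin = label$origin,
                   axes = label$axes)
  write_volume(vol, path)
}
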