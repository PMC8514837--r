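# Retroauricular anatomical coordinate system and probe grid. The origin is
# the most superior point of Henle's spine; the x-axis runs posteriorly
# along the (axial-plane-projected) zygomatic process direction; the y-axis
# is the axial-plane normal oriented superiorly, so the x/y-plane is
# perpendicular to the transversal image plane; z = x cross y points
# laterally on the probed side. Probes are cast along -z (medially).

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the retroauricular coordinate frame from landmarks
#'
#' @param henle Physical position (mm) of the most superior point of Henle's
#'   spine; becomes the frame origin.
#' @param zyg_a,zyg_b Two points (mm) along the center of the zygomatic
#'   process; their difference, projected into the axial plane, orients the
#'   x-axis.
#' @param axial_normal Unit normal of the transversal (axial) image plane,
#'   oriented superiorly; default `c(0, 0, 1)` (canonical RAS superior).
#' @param side `"right"` or `"left"` probed ear. Left ears are mirrored so
#'   +x is posterior on both sides and +z stays lateral (the left frame is
#'   then left-handed by construction).
#' @param posterior_hint Unit vector used only to fix the sign of the
#'   x-axis so +x points posteriorly regardless of the order of the
#'   zygomatic points; default `c(0, -1, 0)` (canonical RAS posterior).
#'   Supply a rotated hint when the scan is not in canonical orientation.
#' @return A `retro_frame` with fields `origin`, `x_axis`, `y_axis`,
#'   `z_axis`, `side`.
#' @export
build_frame <- function(henle, zyg_a, zyg_b, axial_normal = c(0, 0, 1),
                        side = c("right", "left"),
                        posterior_hint = c(0, -1, 0)) {
  side <- match.arg(side)
  henle <- as.numeric(henle)
  v <- as.numeric(zyg_b) - as.numeric(zyg_a)
  if (sqrt(sum(v^2)) == 0)
    stop("build_frame: zygomatic points must be distinct")
  y <- normalize3(as.numeric(axial_normal))
  x <- v - sum(v * y) * y          # project into the axial plane
  if (sqrt(sum(x^2)) < 1e-9 * sqrt(sum(v^2)))
    stop("build_frame: zygomatic direction is parallel to the axial normal ",
         "(degenerate projection)")
  x <- normalize3(x)
  ph <- sum(x * as.numeric(posterior_hint))
  if (ph < 0) x <- -x              # +x posterior
  z <- cross3(x, y)
  if (side == "left") z <- -z      # keep +z lateral on the probed side
  structure(list(origin = henle, x_axis = x, y_axis = y, z_axis = z,
                 side = side),
            class = "retro_frame")
}

#' @export
print.retro_frame <- function(x, ...) {
  cat("Retroauricular frame (", x$side, " ear)\n", sep = "")
  cat("  origin (Henle's spine):", paste(signif(x$origin, 6), collapse = ", "),
      "mm\n")
  for (ax in c("x_axis", "y_axis", "z_axis"))
    cat(" ", ax, ":", paste(signif(x[[ax]], 6), collapse = ", "), "\n")
  invisible(x)
}

frame_basis <- function(frame) cbind(frame$x_axis, frame$y_axis, frame$z_axis)

#' Transform physical points into frame coordinates
#'
#' @param frame A `retro_frame`.
#' @param points n x 3 matrix (or length-3 vector) of physical points (mm).
#' @return n x 3 matrix of frame coordinates (x posterior, y superior,
#'   z lateral).
#' @export
to_frame <- function(frame, points) {
  p <- rbind_points(points)
  sweep(p, 2L, frame$origin, "-") %*% frame_basis(frame)
}

#' Transform frame coordinates into physical points
#'
#' @param frame A `retro_frame`.
#' @param points n x 3 matrix (or length-3 vector) of frame coordinates.
#' @return n x 3 matrix of physical points (mm).
#' @export
from_frame <- function(frame, points) {
  p <- rbind_points(points)
  sweep(p %*% t(frame_basis(frame)), 2L, frame$origin, "+")
}

#' Generate the retroauricular probe grid
#'
#' Regular grid of probe positions in frame (x, y) coordinates, row-major:
#' anterior to posterior (x fastest), then inferior to superior. The default
#' 8 x 8 grid at 5 mm spacing with lower anterior corner (4, -10) mm yields
#' 64 probes covering 35 x 35 mm^2.
#'
#' @param frame A `retro_frame` the grid refers to.
#' @param nx,ny Grid dimensions (>= 1).
#' @param spacing Probe spacing in mm (> 0).
#' @param corner Frame (x, y) of the lower anterior corner, mm.
#' @return A `probe_grid` with fields `nx`, `ny`, `spacing`, `corner`,
#'   `points` (nx*ny x 2 matrix of frame coordinates) and `frame`.
#' @export
make_grid <- function(frame, nx = 8, ny = 8, spacing = 5, corner = c(4, -10)) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0)
  pts <- as.matrix(expand.grid(x = corner[1] + (seq_len(nx) - 1L) * spacing,
                               y = corner[2] + (seq_len(ny) - 1L) * spacing))
  structure(list(nx = as.integer(nx), ny = as.integer(ny), spacing = spacing,
                 corner = corner, points = pts, frame = frame),
            class = "probe_grid")
}

#' @export
print.probe_grid <- function(x, ...) {
  cat("Probe grid:", x$nx, "x", x$ny, "at", x$spacing, "mm spacing;",
      "corner (", paste(x$corner, collapse = ", "), ") mm;",
      nrow(x$points), "probes covering",
      (x$nx - 1) * x$spacing, "x", (x$ny - 1) * x$spacing, "mm^2\n")
  invisible(x)
}

#' Read landmarks from JSON or CSV
#'
#' JSON: an array of objects `{name, x, y, z}` (or a named object of
#' `[x, y, z]` triples). CSV: columns `name, x, y, z`. Recognized names
#' (case-insensitive): `henle`, `zyg_a`/`zygoma_a`, `zyg_b`/`zygoma_b`.
#'
#' @param path File path (`.json` or `.csv`).
#' @return Named list of length-3 numeric vectors
#'   (`henle`, `zyg_a`, `zyg_b`), scanner mm.
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(obj)) {
      lm <- setNames(lapply(seq_len(nrow(obj)),
                            function(i) as.numeric(obj[i, c("x", "y", "z")])),
                     tolower(obj$name))
    } else {
      lm <- setNames(lapply(obj, as.numeric), tolower(names(obj)))
    }
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    lm <- setNames(lapply(seq_len(nrow(tab)),
                          function(i) as.numeric(tab[i, c("x", "y", "z")])),
                   tolower(tab$name))
  }
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(lm[[nm]])) return(lm[[nm]])
    stop("read_landmarks: missing landmark '", ..1, "' in ", path)
  }
  out <- list(henle = pick("henle", "henle_spine"),
              zyg_a = pick("zyg_a", "zygoma_a"),
              zyg_b = pick("zyg_b", "zygoma_b"))
  # optional orientation hints for scans not in canonical orientation
  for (extra in c("axial_normal", "posterior_hint"))
    if (!is.null(lm[[extra]])) out[[extra]] <- lm[[extra]]
  out
}
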