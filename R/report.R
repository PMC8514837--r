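# Cohort aggregation of per-probe tables into grid-cell statistics and
# heat-map rendering. Cells average over the subjects that have a valid
# probe there; cells with no valid probe are marked missing, never
# zero-filled.

#' Aggregate per-probe tables across subjects
#'
#' @param tables List of per-probe data frames (from [probe_table()] or
#'   [read_results()]), all sharing the same grid geometry.
#' @param measure Column to aggregate (e.g. `"d_tb_mm"`, `"cortical_hu"`,
#'   `"cortical_bmd"`, `"sisi_4"`, `"sisi_5"`, `"codi"`).
#' @return A `grid_summary`: per-cell `mean`, `sd` and `n` matrices
#'   (anterior-posterior x inferior-superior), plus the grid coordinates.
#' @export
aggregate_grid <- function(tables, measure) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  ref <- tables[[1]]
  if (!measure %in% names(ref))
    stop("aggregate_grid: no column '", measure, "' in the tables")
  key <- function(t) paste(t$grid_x, t$grid_y)
  ref_key <- sort(key(ref))
  for (t in tables)
    if (!identical(sort(key(t)), ref_key))
      stop("aggregate_grid: tables do not share the same grid geometry")
  xs <- sort(unique(ref$grid_x))
  ys <- sort(unique(ref$grid_y))
  vals <- array(NA_real_, dim = c(length(xs), length(ys), length(tables)))
  for (s in seq_along(tables)) {
    t <- tables[[s]]
    i <- match(t$grid_x, xs)
    j <- match(t$grid_y, ys)
    vals[cbind(i, j, s)] <- as.numeric(t[[measure]])
  }
  n <- apply(vals, c(1, 2), function(v) sum(!is.na(v)))
  mu <- apply(vals, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  sdev <- apply(vals, c(1, 2), function(v)
    if (sum(!is.na(v)) < 2L) NA_real_ else sd(v, na.rm = TRUE))
  structure(list(measure = measure, grid_x = xs, grid_y = ys,
                 mean = mu, sd = sdev, n = n,
                 n_subjects = length(tables)),
            class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat("Grid summary of", x$measure, "over", x$n_subjects, "subject(s):",
      length(x$grid_x), "x", length(x$grid_y), "cells;",
      sum(x$n == 0), "missing\n")
  cat("  mean range:", paste(signif(range(x$mean, na.rm = TRUE), 5),
                             collapse = " .. "), "\n")
  invisible(x)
}

#' Write a grid summary as CSV
#'
#' @param summary A `grid_summary`.
#' @param path Output CSV path (columns `grid_x, grid_y, mean, sd, n`).
#' @return The path, invisibly.
#' @export
write_summary <- function(summary, path) {
  g <- expand.grid(grid_x = summary$grid_x, grid_y = summary$grid_y)
  g$mean <- as.vector(summary$mean)
  g$sd <- as.vector(summary$sd)
  g$n <- as.vector(summary$n)
  write.csv(g, path, row.names = FALSE, na = "")
  invisible(path)
}

.measure_label <- function(measure) {
  switch(measure,
         d_tb_mm = "temporal bone thickness (mm)",
         cortical_hu = "cortical bone density (HU)",
         cortical_bmd = "cortical bone density (mg HA/cm³)",
         codi = "CODI (mg HA/mm²)",
         if (grepl("^sisi_", measure))
           paste0("SISI, d_min = ", sub("sisi_", "", measure), " mm (%)")
         else measure)
}

draw_heatmap <- function(summary, main = NULL) {
  xs <- summary$grid_x
  ys <- summary$grid_y
  z <- summary$mean
  pal <- colorRampPalette(c("#313695", "#74ADD1", "#FFFFBF",
                            "#F46D43", "#A50026"))(64)
  zr <- range(z, na.rm = TRUE)
  if (!all(is.finite(zr))) zr <- c(0, 1)
  if (zr[1] == zr[2]) zr <- zr + c(-0.5, 0.5)
  op <- par(no.readonly = TRUE)
  on.exit(par(op))
  layout(matrix(1:2, nrow = 1), widths = c(4, 1))
  par(mar = c(4.5, 4.5, 3, 0.5))
  image(xs, ys, z, col = pal, zlim = zr, axes = FALSE, asp = 1,
        xlab = "x posterior from Henle's spine (mm)",
        ylab = "y superior from Henle's spine (mm)")
  axis(1, at = xs)
  axis(2, at = ys)
  box()
  # hatch cells with no valid probe
  dx <- if (length(xs) > 1) diff(xs)[1] else 1
  dy <- if (length(ys) > 1) diff(ys)[1] else 1
  miss <- which(summary$n == 0, arr.ind = TRUE)
  if (length(miss)) {
    for (r in seq_len(nrow(miss))) {
      cx <- xs[miss[r, 1]]; cy <- ys[miss[r, 2]]
      rect(cx - dx / 2, cy - dy / 2, cx + dx / 2, cy + dy / 2,
           col = "white", border = "grey60")
      segments(cx - dx / 2, cy - dy / 2, cx + dx / 2, cy + dy / 2,
               col = "grey60")
      segments(cx - dx / 2, cy + dy / 2, cx + dx / 2, cy - dy / 2,
               col = "grey60")
    }
  }
  title(main = if (is.null(main)) .measure_label(summary$measure) else main)
  # color bar
  par(mar = c(4.5, 0.5, 3, 2.5))
  bar <- seq(zr[1], zr[2], length.out = 65)
  image(1, (bar[-1] + bar[-65]) / 2, matrix(seq_len(64), nrow = 1),
        col = pal, axes = FALSE, xlab = "", ylab = "")
  axis(4, at = pretty(zr))
  box()
  mtext(.measure_label(summary$measure), side = 4, line = 1.6, cex = 0.8)
  invisible(list(ticks_x = xs, ticks_y = ys))
}

#' Render a grid summary as a heat map
#'
#' Draws the per-cell means as an 8 x 8 (or whatever the grid is) raster in
#' frame coordinates (x posterior, y superior from Henle's spine), with a
#' unit-labeled color bar; cells without any valid probe are hatched.
#'
#' @param summary A `grid_summary`.
#' @param path Output image path; `.png` or `.svg`.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @param main Optional title (default: the measure's label).
#' @return Invisibly, a list with `ticks_x`, `ticks_y` (the grid coordinates
#'   used as axis ticks) and `path`.
#' @export
render_heatmap <- function(summary, path, width = NULL, height = NULL,
                           main = NULL) {
  stopifnot(inherits(summary, "grid_summary"))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg"))
    stop("render_heatmap: path must end in .png or .svg")
  ok <- tryCatch({
    if (ext == "png")
      png(path, width = if (is.null(width)) 640 else width,
          height = if (is.null(height)) 560 else height, type = "cairo")
    else
      svg(path, width = if (is.null(width)) 7 else width,
          height = if (is.null(height)) 6 else height)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("render_heatmap: cannot open graphics device for ", path)
  on.exit(dev.off())
  ticks <- draw_heatmap(summary, main = main)
  invisible(c(ticks, list(path = path)))
}

#' @export
plot.grid_summary <- function(x, main = NULL, ...) {
  invisible(draw_heatmap(x, main = main))
}
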