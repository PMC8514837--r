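# Minimal single-frame CT DICOM codec: explicit VR little endian,
# uncompressed 16-bit signed pixel data. Covers the geometry and rescale
# tags needed to assemble a calibrated volume from a clinical series.
# DICOM patient coordinates are LPS; volumes are converted to the package's
# canonical RAS-like convention on read (x and y negated).

.dcm_uid_root <- "1.2.826.0.1.3680043.9999"
.dcm_ct_sop_class <- "1.2.840.10008.5.1.4.1.1.2"
.dcm_explicit_le <- "1.2.840.10008.1.2.1"
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                 endian = "little")
.dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                 endian = "little")

.dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

.dcm_str <- function(x, pad = as.raw(0x20)) .dcm_pad(charToRaw(x), pad)

.dcm_ds <- function(x) {
  paste(vapply(x, function(v) formatC(v, digits = 10, format = "g"),
               character(1)), collapse = "\\")
}

.dcm_element <- function(group, elem, vr, value) {
  head <- c(.dcm_u16(group), .dcm_u16(elem), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(head, as.raw(c(0, 0)), .dcm_u32(length(value)), value)
  } else {
    c(head, .dcm_u16(length(value)), value)
  }
}

# deterministic pseudo-UIDs built from a series tag and instance number
.dcm_uid <- function(...) paste(.dcm_uid_root, ..., sep = ".")

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame CT file per axial slice
#' (k index), storing pixel data as signed 16-bit integers with the given
#' rescale slope/intercept so that `stored * slope + intercept` equals HU.
#' Geometry is written in DICOM LPS patient coordinates.
#'
#' @param volume A [ct_volume].
#' @param dir Output directory (created if needed).
#' @param slope,intercept Rescale slope and intercept used to store HU.
#' @param series_id Integer tag used to build deterministic UIDs.
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(volume, dir, slope = 1, intercept = -1024,
                               series_id = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume$data)
  ras_to_lps <- diag(c(-1, -1, 1))
  axes_lps <- ras_to_lps %*% volume$axes
  row_dir <- axes_lps[, 1]  # direction of increasing column index
  col_dir <- axes_lps[, 2]  # direction of increasing row index
  raw_vals <- round((volume$data - intercept) / slope)
  if (any(raw_vals < -32768 | raw_vals > 32767))
    stop("write_dicom_series: rescaled values exceed 16-bit signed range")
  study_uid <- .dcm_uid(series_id, 1)
  series_uid <- .dcm_uid(series_id, 2)
  for (k in seq_len(d[3])) {
    ipp <- as.numeric(ras_to_lps %*%
                        voxel_to_physical(volume, c(0, 0, k - 1))[1, ])
    sop_uid <- .dcm_uid(series_id, 3, k)
    px <- as.integer(raw_vals[, , k])  # column index fastest, per DICOM rows
    pixel_bytes <- writeBin(px, raw(), size = 2L, endian = "little")

    meta <- c(
      .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcm_element(0x0002, 0x0002, "UI", .dcm_str(.dcm_ct_sop_class, as.raw(0))),
      .dcm_element(0x0002, 0x0003, "UI", .dcm_str(sop_uid, as.raw(0))),
      .dcm_element(0x0002, 0x0010, "UI", .dcm_str(.dcm_explicit_le, as.raw(0))),
      .dcm_element(0x0002, 0x0012, "UI", .dcm_str(.dcm_uid(0, 0), as.raw(0)))
    )
    dataset <- c(
      .dcm_element(0x0008, 0x0016, "UI", .dcm_str(.dcm_ct_sop_class, as.raw(0))),
      .dcm_element(0x0008, 0x0018, "UI", .dcm_str(sop_uid, as.raw(0))),
      .dcm_element(0x0008, 0x0060, "CS", .dcm_str("CT")),
      .dcm_element(0x0020, 0x000D, "UI", .dcm_str(study_uid, as.raw(0))),
      .dcm_element(0x0020, 0x000E, "UI", .dcm_str(series_uid, as.raw(0))),
      .dcm_element(0x0020, 0x0013, "IS", .dcm_str(as.character(k))),
      .dcm_element(0x0020, 0x0032, "DS", .dcm_str(.dcm_ds(ipp))),
      .dcm_element(0x0020, 0x0037, "DS",
                   .dcm_str(.dcm_ds(c(row_dir, col_dir)))),
      .dcm_element(0x0028, 0x0002, "US", .dcm_u16(1)),
      .dcm_element(0x0028, 0x0004, "CS", .dcm_str("MONOCHROME2")),
      .dcm_element(0x0028, 0x0010, "US", .dcm_u16(d[2])),  # Rows
      .dcm_element(0x0028, 0x0011, "US", .dcm_u16(d[1])),  # Columns
      .dcm_element(0x0028, 0x0030, "DS",
                   .dcm_str(.dcm_ds(volume$spacing[c(2, 1)]))),
      .dcm_element(0x0028, 0x0100, "US", .dcm_u16(16)),
      .dcm_element(0x0028, 0x0101, "US", .dcm_u16(16)),
      .dcm_element(0x0028, 0x0102, "US", .dcm_u16(15)),
      .dcm_element(0x0028, 0x0103, "US", .dcm_u16(1)),
      .dcm_element(0x0028, 0x1052, "DS", .dcm_str(.dcm_ds(intercept))),
      .dcm_element(0x0028, 0x1053, "DS", .dcm_str(.dcm_ds(slope))),
      .dcm_element(0x7FE0, 0x0010, "OW", pixel_bytes)
    )
    meta_len <- .dcm_element(0x0002, 0x0000, "UL", .dcm_u32(length(meta)))
    path <- file.path(dir, sprintf("slice_%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta_len, meta, dataset), con)
    close(con)
  }
  invisible(dir)
}

# parse one DICOM file; returns a named list of the tags of interest
.dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("read_dicom_series: not a DICOM part-10 file: ", path)
  pos <- 133L
  n <- length(bytes)
  out <- list()
  u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2L,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4L,
                              endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("read_dicom_series: implicit-VR or corrupted element at byte ",
           pos, " in ", path)
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); vpos <- pos + 12L
    } else {
      len <- u16(pos + 6L); vpos <- pos + 8L
    }
    if (len < 0 || vpos + len - 1L > n)
      stop("read_dicom_series: element length overruns file in ", path)
    if (vr == "SQ")
      stop("read_dicom_series: sequence elements are not supported (",
           sprintf("%04X,%04X", group, elem), ") in ", path)
    val <- if (len > 0) bytes[vpos:(vpos + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, value = val)
    pos <- vpos + len
  }
  out
}

.dcm_get <- function(tags, key, path, parse = c("string", "numbers", "u16")) {
  parse <- match.arg(parse)
  el <- tags[[key]]
  if (is.null(el))
    stop("read_dicom_series: missing required tag (", key, ") in ", path)
  if (parse == "u16")
    return(readBin(el$value, "integer", size = 2L, signed = FALSE,
                   endian = "little"))
  s <- trimws(rawToChar(el$value[el$value != as.raw(0)]))
  if (parse == "string") return(s)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

#' Read a DICOM series as a CT volume
#'
#' Reads all `.dcm` files in a directory, checks that they share in-plane
#' spacing and orientation, sorts them along the slice normal, rescales
#' stored values to HU, and returns the volume in the canonical RAS-like
#' convention. Contradictory geometry (mixed orientations, non-uniform slice
#' spacing or in-plane spacing) is a hard error naming the offending field.
#'
#' @param dir Directory containing the series.
#' @return A [ct_volume].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L)
    stop("read_dicom_series: no .dcm files in ", dir)
  slices <- lapply(files, function(f) {
    tags <- .dcm_parse_file(f)
    ts <- tags[["0002,0010"]]
    if (!is.null(ts)) {
      uid <- trimws(rawToChar(ts$value[ts$value != as.raw(0)]))
      if (uid != .dcm_explicit_le)
        stop("read_dicom_series: unsupported transfer syntax ", uid, " in ", f)
    }
    rows <- .dcm_get(tags, "0028,0010", f, "u16")
    cols <- .dcm_get(tags, "0028,0011", f, "u16")
    ipp <- .dcm_get(tags, "0020,0032", f, "numbers")
    iop <- .dcm_get(tags, "0020,0037", f, "numbers")
    ps <- .dcm_get(tags, "0028,0030", f, "numbers")
    bits <- .dcm_get(tags, "0028,0100", f, "u16")
    if (bits != 16L)
      stop("read_dicom_series: only 16-bit pixel data supported (BitsAllocated=",
           bits, ") in ", f)
    signed <- .dcm_get(tags, "0028,0103", f, "u16") == 1L
    slope <- .dcm_get(tags, "0028,1053", f, "numbers")
    inter <- .dcm_get(tags, "0028,1052", f, "numbers")
    if (length(ipp) != 3L)
      stop("read_dicom_series: malformed ImagePositionPatient in ", f)
    if (length(iop) != 6L)
      stop("read_dicom_series: malformed ImageOrientationPatient in ", f)
    px <- tags[["7FE0,0010"]]
    if (is.null(px))
      stop("read_dicom_series: missing required tag (7FE0,0010 PixelData) in ", f)
    vals <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
    if (length(vals) != rows * cols)
      stop("read_dicom_series: PixelData size does not match Rows x Columns in ", f)
    list(rows = rows, cols = cols, ipp = ipp, iop = iop, ps = ps,
         hu = vals * slope + inter, file = f)
  })
  ref <- slices[[1]]
  for (s in slices) {
    if (max(abs(s$iop - ref$iop)) > 1e-6)
      stop("read_dicom_series: mixed slice orientations ",
           "(ImageOrientationPatient differs between slices)")
    if (s$rows != ref$rows || s$cols != ref$cols)
      stop("read_dicom_series: inconsistent Rows/Columns across slices")
    if (max(abs(s$ps - ref$ps)) > 1e-6)
      stop("read_dicom_series: inconsistent PixelSpacing across slices")
  }
  row_dir <- ref$iop[1:3]   # direction of increasing column index (LPS)
  col_dir <- ref$iop[4:6]   # direction of increasing row index (LPS)
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  proj <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(proj)
  slices <- slices[ord]
  proj <- proj[ord]
  if (length(slices) > 1L) {
    gaps <- diff(proj)
    if (any(gaps <= 0) || max(gaps) - min(gaps) > 1e-3)
      stop("read_dicom_series: non-uniform slice spacing ",
           "(ImagePositionPatient gaps differ)")
    dz <- mean(gaps)
  } else dz <- 1
  nx <- ref$cols; ny <- ref$rows; nz <- length(slices)
  data <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz))
    data[, , k] <- slices[[k]]$hu  # stream is column-index fastest
  lps_to_ras <- diag(c(-1, -1, 1))
  axes <- lps_to_ras %*% cbind(row_dir, col_dir, normal)
  origin <- as.numeric(lps_to_ras %*% slices[[1]]$ipp)
  ct_volume(data, spacing = c(ref$ps[2], ref$ps[1], dz),
            origin = origin, axes = axes)
}
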