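## Minimal single-band GeoTIFF I/O.
##
## Little-endian, uncompressed, one sample per pixel. The writer always
## emits Float64 samples plus ModelPixelScale / ModelTiepoint /
## GeoKeyDirectory / GDAL_NODATA tags; the reader additionally accepts the
## common unsigned/signed integer and Float32 layouts so files produced by
## GDAL-based tools can be ingested, but only projected (metre-unit) CRSs.

TIFF_TYPE_SIZES <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                     `6` = 1, `7` = 1, `8` = 2, `9` = 4, `10` = 8,
                     `11` = 4, `12` = 8)

tif_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
tif_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
tif_dbl <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

#' Write a raster layer to a single-band GeoTIFF
#'
#' Cell values are stored as 64-bit floats (bit-exact round-trip for
#' integer-coded layers); `NA` cells are written as the layer's `nodata`
#' sentinel and recorded in the file's nodata tag. Georeferencing is written
#' as a pixel-scale/tiepoint pair plus a GeoKey directory carrying the
#' projected EPSG code; the layer semantics go into the image description so
#' [read_raster()] can restore them. Output is written to a temporary file
#' and renamed into place, so a failed write never leaves a partial raster.
#'
#' @param layer A [raster_layer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_raster()]
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "raster_layer"))
  sp <- layer$spec
  vals <- layer$values
  vals[!is.finite(vals)] <- layer$nodata
  n_px <- sp$n_rows * sp$n_cols
  data_bytes <- 8L * n_px

  # entry layout: header (8) | pixel data | IFD | out-of-line tag values
  tags <- list()
  add <- function(code, type, values, ascii = FALSE)
    tags[[length(tags) + 1L]] <<- list(code = code, type = type,
                                       values = values, ascii = ascii)
  geokeys <- c(1L, 1L, 0L, 3L,            # version, rev 1.0, key count
               1024L, 0L, 1L, 1L,         # model type: projected
               1025L, 0L, 1L, 1L,         # raster type: pixel is area
               3072L, 0L, 1L, sp$crs_id)  # projected CRS EPSG code
  add(256L, 4L, sp$n_cols)
  add(257L, 4L, sp$n_rows)
  add(258L, 3L, 64L)
  add(259L, 3L, 1L)
  add(262L, 3L, 1L)
  add(270L, 2L, layer$semantics, ascii = TRUE)
  add(273L, 4L, 8L)
  add(277L, 3L, 1L)
  add(278L, 4L, sp$n_rows)
  add(279L, 4L, data_bytes)
  add(339L, 3L, 3L)
  add(33550L, 12L, c(sp$cell_size, sp$cell_size, 0))
  add(33922L, 12L, c(0, 0, 0, sp$origin_x, sp$origin_y, 0))
  add(34735L, 3L, geokeys)
  add(42113L, 2L, format(layer$nodata, scientific = FALSE), ascii = TRUE)

  encode <- function(tag) {
    if (tag$ascii) {
      r <- c(writeBin(as.character(tag$values), raw()))  # NUL-terminated
      list(count = length(r), raw = r)
    } else if (tag$type == 3L) {
      list(count = length(tag$values), raw = tif_u16(tag$values))
    } else if (tag$type == 4L) {
      list(count = length(tag$values), raw = tif_u32(tag$values))
    } else {
      list(count = length(tag$values), raw = tif_dbl(tag$values))
    }
  }

  ifd_offset <- 8L + data_bytes
  if (ifd_offset %% 2L == 1L) ifd_offset <- ifd_offset + 1L
  ifd_bytes <- 2L + 12L * length(tags) + 4L
  extra_offset <- ifd_offset + ifd_bytes
  entries <- raw(0); extra <- raw(0)
  for (tag in tags) {
    enc <- encode(tag)
    entry <- c(tif_u16(tag$code), tif_u16(tag$type), tif_u32(enc$count))
    if (length(enc$raw) <= 4L) {
      entry <- c(entry, enc$raw, raw(4L - length(enc$raw)))
    } else {
      entry <- c(entry, tif_u32(extra_offset + length(extra)))
      if (length(enc$raw) %% 2L == 1L) enc$raw <- c(enc$raw, raw(1))
      extra <- c(extra, enc$raw)
    }
    entries <- c(entries, entry)
  }

  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tif")
  con <- try(file(tmp, "wb"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write raster to '", path, "'", call. = FALSE)
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  writeBin(charToRaw("II"), con)
  writeBin(tif_u16(42L), con)
  writeBin(tif_u32(ifd_offset), con)
  writeBin(as.vector(t(vals)), con, size = 8, endian = "little")
  if (8L + data_bytes < ifd_offset) writeBin(raw(1), con)
  writeBin(tif_u16(length(tags)), con)
  writeBin(entries, con)
  writeBin(tif_u32(0L), con)
  writeBin(extra, con)
  close(con)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("cannot write raster to '", path, "'", call. = FALSE)
  }
  invisible(path)
}

read_tiff_values <- function(buf, pos, type, count, endian) {
  size <- TIFF_TYPE_SIZES[[as.character(type)]]
  nbytes <- size * count
  slice <- if (nbytes <= 4L) buf[pos:(pos + 3L)] else {
    off <- readBin(buf[pos:(pos + 3L)], "integer", size = 4, endian = endian)
    buf[(off + 1L):(off + nbytes)]
  }
  switch(as.character(type),
    `2` = rawToChar(slice[seq_len(max(count - 1L, 0L))]),
    `3` = readBin(slice, "integer", n = count, size = 2, signed = FALSE,
                  endian = endian),
    `4` = readBin(slice, "integer", n = count, size = 4, endian = endian),
    `8` = readBin(slice, "integer", n = count, size = 2, signed = TRUE,
                  endian = endian),
    `9` = readBin(slice, "integer", n = count, size = 4, endian = endian),
    `11` = readBin(slice, "double", n = count, size = 4, endian = endian),
    `12` = readBin(slice, "double", n = count, size = 8, endian = endian),
    NULL)
}

#' Read a single-band GeoTIFF into a raster layer
#'
#' Supports uncompressed, stripped, single-band files with integer or
#' floating-point samples in a projected CRS. Cells equal to the file's
#' nodata value (or `nodata`, if the file carries none) become `NA`.
#'
#' @param path Path to a GeoTIFF file.
#' @param semantics Layer semantics; defaults to the tag stored in the
#'   file's image description, else `"cover_pct"`.
#' @param nodata Fallback nodata value when the file has no nodata tag.
#' @return A [raster_layer()].
#' @examples
#' sp <- grid_spec(0, 90, 30, 3, 3)
#' f <- tempfile(fileext = ".tif")
#' write_raster(raster_layer(matrix(0:8, 3, 3), sp, "sci"), f)
#' read_raster(f)
#' @export
read_raster <- function(path, semantics = NULL, nodata = NULL) {
  if (!file.exists(path))
    stop("raster file '", path, "' does not exist", call. = FALSE)
  buf <- readBin(path, "raw", file.size(path))
  order_mark <- rawToChar(buf[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("'", path, "' is not a TIFF file", call. = FALSE))
  ifd_off <- readBin(buf[5:8], "integer", size = 4, endian = endian)
  n_entries <- readBin(buf[(ifd_off + 1L):(ifd_off + 2L)], "integer",
                       size = 2, signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    base <- ifd_off + 2L + (i - 1L) * 12L
    code <- readBin(buf[(base + 1L):(base + 2L)], "integer", size = 2,
                    signed = FALSE, endian = endian)
    type <- readBin(buf[(base + 3L):(base + 4L)], "integer", size = 2,
                    signed = FALSE, endian = endian)
    count <- readBin(buf[(base + 5L):(base + 8L)], "integer", size = 4,
                     endian = endian)
    tags[[as.character(code)]] <-
      read_tiff_values(buf, base + 9L, type, count, endian)
  }
  tg <- function(code, default = NULL) {
    v <- tags[[as.character(code)]]
    if (is.null(v)) default else v
  }

  n_cols <- tg(256); n_rows <- tg(257)
  if (is.null(n_cols) || is.null(n_rows))
    stop("'", path, "' lacks image dimensions", call. = FALSE)
  if (tg(277, 1L) != 1L || length(tg(258, 1L)) != 1L)
    stop("'", path, "' is multi-band; only single-band rasters are supported",
         call. = FALSE)
  if (tg(259, 1L) != 1L)
    stop("'", path, "' is compressed; only uncompressed TIFF is supported",
         call. = FALSE)

  geokeys <- tg(34735)
  crs_id <- NA_integer_
  if (!is.null(geokeys) && length(geokeys) >= 4L) {
    nk <- geokeys[4]
    for (k in seq_len(nk)) {
      key <- geokeys[4 * k + 1:4]
      if (key[1] == 1024 && key[4] == 2)
        stop("'", path, "' is in a geographic (degree-unit) CRS; ",
             "project it to a metric CRS first", call. = FALSE)
      if (key[1] == 2048)
        stop("'", path, "' carries a geographic CRS code; ",
             "project it to a metric CRS first", call. = FALSE)
      if (key[1] == 3072) crs_id <- as.integer(key[4])
    }
  }
  scale <- tg(33550); tiepoint <- tg(33922)
  if (is.null(scale) || is.null(tiepoint))
    stop("'", path, "' lacks georeferencing tags", call. = FALSE)
  if (abs(scale[1] - scale[2]) > 1e-9 * scale[1])
    stop("'", path, "' has non-square cells", call. = FALSE)
  cell <- scale[1]
  origin_x <- tiepoint[4] - tiepoint[1] * cell
  origin_y <- tiepoint[5] + tiepoint[2] * cell
  spec <- grid_spec(origin_x, origin_y, cell, n_rows, n_cols,
                    if (is.na(crs_id)) 32722L else crs_id)

  bits <- tg(258); fmt <- tg(339, 1L)
  offsets <- tg(273); counts <- tg(279)
  rows_per_strip <- tg(278, n_rows)
  bytes_px <- bits %/% 8L
  vals <- numeric(0)
  for (s in seq_along(offsets)) {
    nb <- counts[s]
    slice <- buf[(offsets[s] + 1L):(offsets[s] + nb)]
    n <- nb %/% bytes_px
    vals <- c(vals, if (fmt == 3L) {
      readBin(slice, "double", n = n, size = bytes_px, endian = endian)
    } else if (fmt == 2L) {
      readBin(slice, "integer", n = n, size = bytes_px, endian = endian)
    } else if (bytes_px == 4L) {
      v <- readBin(slice, "integer", n = n, size = 4, endian = endian)
      ifelse(v < 0, v + 2^32, v)
    } else {
      readBin(slice, "integer", n = n, size = bytes_px, signed = FALSE,
              endian = endian)
    })
  }
  m <- matrix(vals, n_rows, n_cols, byrow = TRUE)

  nd_tag <- tg(42113)
  nd <- if (!is.null(nd_tag)) as.numeric(trimws(nd_tag))
        else if (!is.null(nodata)) nodata
  sem <- semantics %||% tg(270)
  if (is.null(sem) || !sem %in% raster_semantics) sem <- "density"
  if (is.null(nd) || is.na(nd)) nd <- default_nodata(sem)
  m[m == nd] <- NA_real_
  raster_layer(m, spec, sem, nodata = nd)
}
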