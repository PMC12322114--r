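# Compact single-band GeoTIFF codec (classic TIFF, uncompressed).
#
# Scope is deliberately narrow: one band, IEEE-float samples (64-bit by
# default, 32-bit behind a flag), single planar configuration, strip
# layout, little-endian on write (either byte order on read). Georeference
# is carried by the ModelPixelScale + ModelTiepoint tags, the CRS by a
# minimal GeoKey directory (projected CS key), and nodata by the GDAL
# nodata ASCII tag. Files without a transform or a nodata tag are refused:
# downstream arithmetic needs both.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

#' Write a grid to a single-band GeoTIFF file
#'
#' Values are stored as IEEE floats (64-bit by default), one sample per
#' pixel, uncompressed, with the affine transform (ModelPixelScale and
#' ModelTiepoint tags), the projected CRS (GeoKey directory) and the
#' nodata sentinel (GDAL nodata tag). `NA` cells are written as the
#' grid's nodata sentinel. With `float32 = FALSE` a write/read round trip
#' reproduces the values bit-exactly.
#'
#' @param g a [grid_create()] grid.
#' @param path output file path.
#' @param float32 write 32-bit floats instead of 64-bit (smaller files,
#'   lossy for values that are not exactly representable).
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path, float32 = FALSE) {
  stopifnot(inherits(g, "grid"))
  v <- g$values
  v[is.na(v)] <- g$nodata
  nr <- nrow(v); nc <- ncol(v)
  bits <- if (float32) 32L else 64L
  bytes_px <- bits %/% 8L
  nodata_str <- c(charToRaw(format(g$nodata, scientific = FALSE, trim = TRUE)),
                  as.raw(0))
  if (length(nodata_str) %% 2L == 1L) nodata_str <- c(nodata_str, as.raw(0))

  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 1,     # model type: projected
                          1025, 0, 1, 1,     # raster type: pixel-is-area
                          3072, 0, 1, g$crs))

  n_tags <- 15L
  ifd_off <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  off_scale <- ifd_off + ifd_size
  off_tie <- off_scale + 24L
  off_keys <- off_tie + 48L
  off_nodata <- off_keys + 2L * length(geokeys)
  off_data <- off_nodata + length(nodata_str)
  strip_bytes <- nr * nc * bytes_px

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")

  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  tag_short_inline <- function(id, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(3L, con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }

  writeBin(n_tags, con, size = 2, endian = "little")
  tag(256, 4, 1, nc)                       # ImageWidth
  tag(257, 4, 1, nr)                       # ImageLength
  tag_short_inline(258, bits)              # BitsPerSample
  tag_short_inline(259, 1)                 # Compression: none
  tag_short_inline(262, 1)                 # Photometric: BlackIsZero
  tag(273, 4, 1, off_data)                 # StripOffsets
  tag_short_inline(277, 1)                 # SamplesPerPixel
  tag(278, 4, 1, nr)                       # RowsPerStrip
  tag(279, 4, 1, strip_bytes)              # StripByteCounts
  tag_short_inline(284, 1)                 # PlanarConfig: chunky
  tag_short_inline(339, 3)                 # SampleFormat: IEEE float
  tag(33550, 12, 3, off_scale)             # ModelPixelScale
  tag(33922, 12, 6, off_tie)               # ModelTiepoint
  tag(34735, 3, length(geokeys), off_keys) # GeoKeyDirectory
  tag(42113, 2, length(nodata_str), off_nodata)  # GDAL nodata
  writeBin(0L, con, size = 4, endian = "little")  # next IFD: none

  writeBin(c(g$dx, g$dy, 0), con, size = 8, endian = "little")
  writeBin(c(0, 0, 0, g$x0, g$y0, 0), con, size = 8, endian = "little")
  writeBin(geokeys, con, size = 2, endian = "little")
  writeBin(nodata_str, con)
  writeBin(as.vector(t(v)), con, size = bytes_px, endian = "little")
  invisible(path)
}

#' Read a single-band GeoTIFF file into a grid
#'
#' Accepts uncompressed single-band IEEE-float (32/64-bit) classic TIFF
#' in either byte order, with ModelPixelScale/ModelTiepoint georeference
#' and a GDAL nodata tag; sentinel-valued cells become `NA`. Files
#' missing the transform or the nodata tag fail with an explicit error.
#'
#' @param path file path.
#' @param units units declaration to attach to the grid (metadata only).
#' @return a `grid`.
#' @export
read_grid <- function(path, units = "ha") {
  raw <- readBin(path, "raw", file.size(path))
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  rd_int <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4)
  rd_uint <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = FALSE)
  if (rd_int(2, 2) != 42L) stop("not a classic TIFF file: ", path)
  ifd <- rd_int(4, 4)
  n_tags <- rd_int(ifd, 2)

  tags <- list()
  for (k in seq_len(n_tags) - 1L) {
    off <- ifd + 2L + 12L * k
    id <- rd_uint(off, 2)
    type <- rd_uint(off + 2, 2)
    count <- rd_int(off + 4, 4)
    tsize <- TIFF_TYPE_SIZE[[as.character(type)]]
    nbytes <- tsize * count
    voff <- if (nbytes <= 4L) off + 8L else rd_int(off + 8, 4)
    val <- switch(
      as.character(type),
      `2` = {
        seg <- raw[(voff + 1):(voff + count)]
        seg <- seg[cumsum(seg == as.raw(0)) == 0]  # stop at NUL terminator
        rawToChar(seg)
      },
      `3` = rd_uint(voff, 2, count),
      `4` = rd_int(voff, 4, count),
      `12` = readBin(raw[(voff + 1):(voff + 8 * count)], "double", n = count,
                     size = 8, endian = endian),
      NULL)
    tags[[as.character(id)]] <- val
  }

  need <- function(id, what) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) stop("GeoTIFF missing required ", what, " tag: ", path)
    v
  }
  nc <- need(256, "ImageWidth"); nr <- need(257, "ImageLength")
  bits <- need(258, "BitsPerSample")
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
    stop("compressed TIFF not supported: ", path)
  sf <- tags[["339"]]
  if (is.null(sf) || sf != 3L) stop("expected IEEE-float samples: ", path)
  if (!bits %in% c(32L, 64L)) stop("unsupported bit depth: ", bits)
  scale <- need(33550, "ModelPixelScale (transform)")
  tie <- need(33922, "ModelTiepoint (transform)")
  nod_str <- need(42113, "nodata")
  nodata <- suppressWarnings(as.numeric(nod_str))
  if (is.na(nodata)) stop("unparseable nodata tag: ", path)
  crs <- 0L
  gk <- tags[["34735"]]
  if (!is.null(gk) && length(gk) >= 4) {
    nk <- gk[4]
    for (k in seq_len(nk)) {
      key <- gk[4 * k + 1]
      if (!is.na(key) && key == 3072) crs <- gk[4 * k + 4]
    }
  }

  offs <- need(273, "StripOffsets")
  counts <- need(279, "StripByteCounts")
  bytes_px <- bits %/% 8L
  vals <- numeric(0)
  for (s in seq_along(offs)) {
    seg <- raw[(offs[s] + 1):(offs[s] + counts[s])]
    if (bits == 64L) {
      vals <- c(vals, readBin(seg, "double", n = counts[s] %/% 8L, size = 8,
                              endian = endian))
    } else {
      vals <- c(vals, readBin(seg, "double", n = counts[s] %/% 4L, size = 4,
                              endian = endian))
    }
  }
  if (length(vals) != nr * nc) stop("pixel count mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  # tiepoint maps raster (0,0) to map (x,y): top-left corner
  grid_create(m, x0 = tie[4] - tie[1] * scale[1],
              y0 = tie[5] + tie[2] * scale[2],
              dx = scale[1], dy = scale[2],
              nodata = nodata, units = units, crs = crs)
}
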