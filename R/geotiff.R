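# Minimal single-band GeoTIFF codec: uncompressed float32/float64 (and the
# common unsigned-integer layouts on read), one sample per pixel, with the
# ModelPixelScale / ModelTiepoint / GDAL_NODATA tags. Deliberately small:
# no compression, no tiling, no reprojection.

.TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

.read_uint32 <- function(con, endian) {
  v <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  if (v < 0) v <- v + 2^32
  v
}

.read_values <- function(con, type, count, endian) {
  switch(as.character(type),
    `1` = readBin(con, "integer", n = count, size = 1L, signed = FALSE, endian = endian),
    `2` = {
      r <- readBin(con, "raw", n = count)
      rawToChar(r[r != as.raw(0L)])
    },
    `3` = readBin(con, "integer", n = count, size = 2L, signed = FALSE, endian = endian),
    `4` = vapply(seq_len(count), function(i) .read_uint32(con, endian), numeric(1)),
    `11` = readBin(con, "double", n = count, size = 4L, endian = endian),
    `12` = readBin(con, "double", n = count, size = 8L, endian = endian),
    stop("unsupported TIFF field type: ", type))
}

# Parse the first IFD of a TIFF file into a named list of tag values.
.read_ifd <- function(con) {
  magic <- readChar(con, 2L, useBytes = TRUE)
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark)"))
  fortytwo <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE, endian = endian)
  if (fortytwo != 42L) stop("not a TIFF file (bad magic number)")
  ifd_off <- .read_uint32(con, endian)
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE, endian = endian)
  entries <- vector("list", n_entries)
  tags <- integer(n_entries)
  for (i in seq_len(n_entries)) {
    seek(con, ifd_off + 2L + (i - 1L) * 12L)
    tag <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE, endian = endian)
    count <- .read_uint32(con, endian)
    size <- .TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(size)) next
    nbytes <- size * count
    if (nbytes > 4) {
      off <- .read_uint32(con, endian)
      seek(con, off)
    }
    entries[[i]] <- .read_values(con, type, count, endian)
    tags[i] <- tag
  }
  names(entries) <- tags
  attr(entries, "endian") <- endian
  entries
}

# Read a single-band GeoTIFF; returns list(values, xmin, ymax, xres, yres,
# nodata). values is a numeric matrix with row 1 = top (north) row and
# nodata cells set to NA.
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ifd <- .read_ifd(con)
  endian <- attr(ifd, "endian")
  need <- function(tag) {
    v <- ifd[[as.character(tag)]]
    if (is.null(v)) stop("TIFF missing required tag ", tag)
    v
  }
  width <- as.integer(need(256)); height <- as.integer(need(257))
  spp <- ifd[["277"]]
  if (!is.null(spp) && spp != 1L)
    stop("multi-band TIFF (", spp, " samples per pixel): only single-band rasters are supported")
  compression <- ifd[["259"]]
  if (!is.null(compression) && compression != 1L)
    stop("compressed TIFF (compression=", compression, "): only uncompressed rasters are supported")
  bits <- as.integer(need(258))
  fmt <- if (is.null(ifd[["339"]])) 1L else as.integer(ifd[["339"]])
  offsets <- need(273)
  counts <- need(279)
  pixels <- numeric(0)
  for (k in seq_along(offsets)) {
    seek(con, offsets[k])
    n_here <- switch(as.character(fmt),
      `1` = , `2` = counts[k] / (bits / 8L),
      `3` = counts[k] / (bits / 8L),
      stop("unsupported sample format: ", fmt))
    chunk <- if (fmt == 3L) {
      readBin(con, "double", n = n_here, size = bits / 8L, endian = endian)
    } else if (bits == 8L) {
      readBin(con, "integer", n = n_here, size = 1L, signed = (fmt == 2L), endian = endian)
    } else if (bits == 16L) {
      readBin(con, "integer", n = n_here, size = 2L, signed = (fmt == 2L), endian = endian)
    } else if (bits == 32L) {
      v <- readBin(con, "integer", n = n_here, size = 4L, endian = endian)
      if (fmt == 1L) v <- ifelse(v < 0, v + 2^32, v)
      v
    } else stop("unsupported integer bit depth: ", bits)
    pixels <- c(pixels, as.numeric(chunk))
  }
  if (length(pixels) != width * height)
    stop("TIFF pixel count mismatch: got ", length(pixels), ", expected ", width * height)
  values <- matrix(pixels, nrow = height, ncol = width, byrow = TRUE)
  nodata <- NA_real_
  nd_tag <- ifd[["42113"]]
  if (!is.null(nd_tag)) {
    nodata <- suppressWarnings(as.numeric(nd_tag))
    if (!is.na(nodata)) values[values == nodata] <- NA_real_
  }
  scale <- ifd[["33550"]]
  tie <- ifd[["33922"]]
  xres <- if (is.null(scale)) 1 else scale[1]
  yres <- if (is.null(scale)) 1 else scale[2]
  xmin <- if (is.null(tie)) 0 else tie[4] - tie[1] * xres
  ymax <- if (is.null(tie)) height * yres else tie[5] + tie[2] * yres
  list(values = values, xmin = xmin, ymax = ymax, xres = xres, yres = yres,
       nodata = nodata)
}

.tiff_entry <- function(tag, type, count, value_or_offset) {
  # returns a 12-byte raw IFD entry (little-endian)
  c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    value_or_offset)
}

.pad4 <- function(x) {
  if (length(x) >= 4L) return(x[1:4])
  c(x, raw(4L - length(x)))
}

# Write a single-band GeoTIFF (little-endian, uncompressed, one strip).
# values: numeric matrix, row 1 = top row, NA = nodata.
write_geotiff <- function(values, path, xmin = 0, ymax = nrow(values),
                          xres = 1, yres = 1, nodata = -9999,
                          datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  size <- if (datatype == "float32") 4L else 8L
  height <- nrow(values); width <- ncol(values)
  v <- as.numeric(t(values))        # row-major, top row first
  v[is.na(v)] <- nodata
  pix <- writeBin(v, raw(), size = size, endian = "little")

  data_off <- 8L
  n_pix_bytes <- length(pix)
  aux_off <- data_off + n_pix_bytes       # geo doubles + nodata string live here
  scale_bytes <- writeBin(c(xres, yres, 0), raw(), size = 8L, endian = "little")
  tie_bytes <- writeBin(c(0, 0, 0, xmin, ymax, 0), raw(), size = 8L, endian = "little")
  nd_str <- sprintf("%.17g", nodata)
  nd_bytes <- c(charToRaw(nd_str), as.raw(0L))
  geokeys <- as.integer(c(1, 1, 0, 2,       # version, revision, minor, n keys
                          1024, 0, 1, 1,    # GTModelType = projected
                          1025, 0, 1, 1))   # GTRasterType = PixelIsArea
  gk_bytes <- writeBin(geokeys, raw(), size = 2L, endian = "little")
  scale_off <- aux_off
  tie_off <- scale_off + length(scale_bytes)
  gk_off <- tie_off + length(tie_bytes)
  nd_off <- gk_off + length(gk_bytes)
  ifd_off <- nd_off + length(nd_bytes)
  ifd_off <- ifd_off + (ifd_off %% 2L)      # keep IFD word-aligned

  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  u16v <- function(x) .pad4(writeBin(as.integer(x), raw(), size = 2L, endian = "little"))
  entries <- list(
    .tiff_entry(256, 4, 1, u32(width)),
    .tiff_entry(257, 4, 1, u32(height)),
    .tiff_entry(258, 3, 1, u16v(size * 8L)),
    .tiff_entry(259, 3, 1, u16v(1L)),         # no compression
    .tiff_entry(262, 3, 1, u16v(1L)),         # BlackIsZero
    .tiff_entry(273, 4, 1, u32(data_off)),
    .tiff_entry(277, 3, 1, u16v(1L)),
    .tiff_entry(278, 4, 1, u32(height)),
    .tiff_entry(279, 4, 1, u32(n_pix_bytes)),
    .tiff_entry(284, 3, 1, u16v(1L)),
    .tiff_entry(339, 3, 1, u16v(3L)),         # IEEE float
    .tiff_entry(33550, 12, 3, u32(scale_off)),
    .tiff_entry(33922, 12, 6, u32(tie_off)),
    .tiff_entry(34735, 3, length(geokeys), u32(gk_off)),
    .tiff_entry(42113, 2, length(nd_bytes), u32(nd_off))
  )
  ifd <- c(writeBin(length(entries), raw(), size = 2L, endian = "little"),
           unlist(entries),
           u32(0L))                           # no next IFD

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4L, endian = "little")
  writeBin(pix, con)
  writeBin(scale_bytes, con)
  writeBin(tie_bytes, con)
  writeBin(gk_bytes, con)
  writeBin(nd_bytes, con)
  pad <- ifd_off - (nd_off + length(nd_bytes))
  if (pad > 0) writeBin(raw(pad), con)
  writeBin(ifd, con)
  invisible(path)
}

# Round a numeric vector through IEEE single precision (what a float32
# GeoTIFF stores). Used to state round-trip guarantees exactly.
float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}
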