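# Minimal GeoTIFF support: single-band, uncompressed, IEEE-float samples,
# geographic (EPSG:4326) georeference via ModelPixelScale + ModelTiepoint,
# nodata via the GDAL_NODATA ASCII tag. Writing is always little-endian
# float32 in one strip; reading accepts either byte order, float32/float64,
# and any strip layout.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

read_geotiff <- function(path, name) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic, as.raw(c(0x4d, 0x4d)))) "big"
            else stop("format error: not a TIFF file: ", path)
  ri <- function(n, size, signed = FALSE)
    readBin(con, "integer", n = n, size = size, endian = endian,
            signed = signed || size == 4)
  if (ri(1, 2) != 42L) stop("format error: bad TIFF version in ", path)
  ifd_off <- ri(1, 4)
  seek(con, ifd_off)
  n_entries <- ri(1, 2)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- ri(1, 2); typ <- ri(1, 2); cnt <- ri(1, 4)
    payload <- readBin(con, "raw", 4)
    tags[[as.character(tag)]] <- list(type = typ, count = cnt, payload = payload)
  }
  val <- function(tag) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) return(NULL)
    sz <- TIFF_TYPE_SIZE[[as.character(e$type)]]
    nbytes <- sz * e$count
    raw <- if (nbytes <= 4) e$payload[seq_len(nbytes)] else {
      seek(con, readBin(e$payload, "integer", size = 4, endian = endian))
      readBin(con, "raw", nbytes)
    }
    switch(as.character(e$type),
           `2` = rawToChar(raw[raw != as.raw(0)]),
           `3` = readBin(raw, "integer", n = e$count, size = 2,
                         endian = endian, signed = FALSE),
           `4` = readBin(raw, "integer", n = e$count, size = 4, endian = endian),
           `11` = readBin(raw, "double", n = e$count, size = 4, endian = endian),
           `12` = readBin(raw, "double", n = e$count, size = 8, endian = endian),
           stop("unsupported TIFF tag type ", e$type))
  }
  width <- val(256); height <- val(257)
  if (is.null(width) || is.null(height))
    stop("format error: TIFF lacks image dimensions")
  bits <- val(258); if (is.null(bits)) bits <- 1L
  if (!is.null(val(259)) && val(259) != 1L)
    stop("format error: compressed TIFF is not supported")
  fmt <- val(339)
  if (is.null(fmt) || fmt[1] != 3L || !bits[1] %in% c(32L, 64L))
    stop("format error: only IEEE-float GeoTIFF samples are supported")
  if (!is.null(val(277)) && val(277) != 1L)
    stop("format error: only single-band GeoTIFF is supported")
  offs <- val(273); counts <- val(279)
  if (is.null(offs) || is.null(counts))
    stop("format error: TIFF lacks strip layout")
  sz <- bits[1] / 8L
  vals <- unlist(lapply(seq_along(offs), function(i) {
    seek(con, offs[i])
    readBin(con, "double", n = counts[i] / sz, size = sz, endian = endian)
  }))
  if (length(vals) != width * height)
    stop("format error: TIFF pixel count mismatch")
  scale <- val(33550); tie <- val(33922)
  if (is.null(scale) || is.null(tie))
    stop("format error: TIFF lacks a georeference (ModelPixelScale/Tiepoint)")
  if (abs(scale[1] - scale[2]) > 1e-9 * scale[1])
    stop("format error: non-square cells are not supported")
  nodata <- suppressWarnings(as.numeric(val(42113)))
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  m[is.nan(m)] <- NA_real_
  if (length(nodata) == 1 && is.finite(nodata)) m[m == nodata] <- NA_real_
  # tiepoint maps raster (i, j) to model (x, y): west/north of pixel (0, 0)
  west <- tie[4] - tie[1] * scale[1]
  north <- tie[5] + tie[2] * scale[2]
  spec <- grid_spec(height, width, west = west, north = north,
                    cell_deg = scale[1],
                    nodata = if (length(nodata) == 1 && is.finite(nodata))
                      nodata else -9999)
  raster_grid(m, spec, name)
}

write_geotiff <- function(grid, path) {
  spec <- grid$spec
  m <- grid$values
  m[is.na(m)] <- spec$nodata
  pix <- as.vector(t(m))                       # row-major strip
  n_pix_bytes <- length(pix) * 4L
  nodata_str <- c(charToRaw(format(spec$nodata, scientific = FALSE,
                                   trim = TRUE)), as.raw(0L))
  # keep the ASCII value out-of-line (> 4 bytes) so reader and writer agree
  if (length(nodata_str) <= 4L)
    nodata_str <- c(nodata_str, rep(as.raw(0L), 5L - length(nodata_str)))
  # out-of-line blocks appended after the IFD
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 2,      # model type: geographic
                          1025, 0, 1, 1,      # raster type: pixel-is-area
                          2048, 0, 1, 4326))  # WGS84
  entries <- list( # tag, type, count, value (NA value => out-of-line block id)
    list(256L, 4L, 1L, spec$n_cols),
    list(257L, 4L, 1L, spec$n_rows),
    list(258L, 3L, 1L, 32L),
    list(259L, 3L, 1L, 1L),
    list(262L, 3L, 1L, 1L),
    list(273L, 4L, 1L, 8L),                    # pixels start right after header
    list(277L, 3L, 1L, 1L),
    list(278L, 4L, 1L, spec$n_rows),
    list(279L, 4L, 1L, n_pix_bytes),
    list(339L, 3L, 1L, 3L),
    list(33550L, 12L, 3L, "scale"),
    list(33922L, 12L, 6L, "tie"),
    list(34735L, 3L, length(geokeys), "geokeys"),
    list(42113L, 2L, length(nodata_str), "nodata"))
  blocks <- list(
    scale = list(type = "double", data = c(spec$cell_deg, spec$cell_deg, 0)),
    tie = list(type = "double", data = c(0, 0, 0, spec$west, spec$north, 0)),
    geokeys = list(type = "short", data = geokeys),
    nodata = list(type = "raw", data = nodata_str))
  block_size <- function(b) switch(b$type, double = 8L * length(b$data),
                                   short = 2L * length(b$data),
                                   raw = length(b$data))
  ifd_off <- 8L + n_pix_bytes
  data_off <- ifd_off + 2L + 12L * length(entries) + 4L
  offs <- list(); cur <- data_off
  for (nm in names(blocks)) {
    offs[[nm]] <- cur
    cur <- cur + block_size(blocks[[nm]])
    if (cur %% 2L == 1L) cur <- cur + 1L       # word-align blocks
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w_int <- function(x, size) writeBin(as.integer(x), con, size = size,
                                      endian = "little")
  writeBin(as.raw(c(0x49, 0x49)), con); w_int(42L, 2L); w_int(ifd_off, 4L)
  writeBin(pix, con, size = 4L, endian = "little")
  w_int(length(entries), 2L)
  for (e in entries) {
    w_int(e[[1]], 2L); w_int(e[[2]], 2L); w_int(e[[3]], 4L)
    v <- e[[4]]
    if (is.character(v)) {
      w_int(offs[[v]], 4L)
    } else if (e[[2]] == 3L) {                 # SHORT packed left-justified
      w_int(v, 2L); w_int(0L, 2L)
    } else {
      w_int(v, 4L)
    }
  }
  w_int(0L, 4L)                                # no further IFD
  pos <- data_off
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    switch(b$type,
           double = writeBin(as.numeric(b$data), con, size = 8L,
                             endian = "little"),
           short = writeBin(as.integer(b$data), con, size = 2L,
                            endian = "little"),
           raw = writeBin(b$data, con))
    pos <- pos + block_size(b)
    if (pos %% 2L == 1L) { writeBin(as.raw(0), con); pos <- pos + 1L }
  }
  invisible(path)
}
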