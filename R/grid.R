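#' Geographic grid specification
#'
#' Describes a regular latitude/longitude lattice with square cells,
#' rows ordered north to south and columns west to east. Cell bounds are
#' half-open: `[west, east)` in longitude and `(south, north]` in latitude,
#' so every point belongs to exactly one cell.
#'
#' @param n_rows,n_cols Positive integers, lattice dimensions.
#' @param west Longitude of the western outer edge, in `[-180, 180)`.
#' @param north Latitude of the northern outer edge, in `(-90, 90]`.
#' @param cell_deg Angular cell size in decimal degrees (square cells).
#' @param nodata Sentinel value used when writing missing cells to disk.
#'   In memory missing cells are always `NA`.
#'
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, west, north, cell_deg, nodata = -9999) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_deg) == 1)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be positive")
  if (!is.finite(cell_deg) || cell_deg <= 0) stop("cell_deg must be positive")
  if (west < -180 || west >= 180) stop("west must lie in [-180, 180)")
  if (north <= -90 || north > 90) stop("north must lie in (-90, 90]")
  if (n_rows * cell_deg > 180 + 1e-9) stop("grid exceeds 180 degrees of latitude")
  if (n_cols * cell_deg > 360 + 1e-9) stop("grid exceeds 360 degrees of longitude")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, west = west, north = north,
         cell_deg = cell_deg, nodata = nodata),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg; west %g, north %g (south %g, east %g)\n",
              x$n_rows, x$n_cols, x$cell_deg, x$west, x$north,
              x$north - x$n_rows * x$cell_deg, x$west + x$n_cols * x$cell_deg))
  invisible(x)
}

spec_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$west - b$west) < tol && abs(a$north - b$north) < tol &&
    abs(a$cell_deg - b$cell_deg) < tol
}

#' Latitude of cell-row centres / longitude of cell-column centres
#'
#' @param spec A [grid_spec()].
#' @return Numeric vector of row-centre latitudes (north to south) or
#'   column-centre longitudes (west to east).
#' @export
row_centers <- function(spec) {
  spec$north - (seq_len(spec$n_rows) - 0.5) * spec$cell_deg
}

#' @rdname row_centers
#' @export
col_centers <- function(spec) {
  spec$west + (seq_len(spec$n_cols) - 0.5) * spec$cell_deg
}

#' Named geographic raster layer
#'
#' A matrix of cell values tied to a [grid_spec()]. Values are stored with
#' `NA` for missing cells; the spec's `nodata` sentinel is only used in file
#' I/O.
#'
#' @param values Numeric matrix, `n_rows x n_cols`, rows north to south.
#' @param spec A [grid_spec()].
#' @param name Non-empty layer name (e.g. `"bio1"`, `"suitability"`).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, spec, name) {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("values matrix does not match grid_spec dimensions")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("layer name must be a non-empty string")
  storage.mode(values) <- "double"
  if (any(is.infinite(values)))
    stop("raster values must be finite or NA")
  structure(list(values = values, spec = spec, name = name),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<raster_grid> '%s' %d x %d (%d data cells; range %s)\n",
              x$name, x$spec$n_rows, x$spec$n_cols, length(v),
              if (length(v)) paste(signif(range(v), 4), collapse = " .. ") else "empty"))
  invisible(x)
}

#' Stack of co-registered raster layers
#'
#' All layers must share one identical [grid_spec()]; a mismatch is an
#' error, never silently resampled.
#'
#' @param layers A list of [raster_grid()] objects (names taken from the
#'   layers themselves).
#' @param scenario Scenario tag, e.g. `"near_current"`, `"SSP1-2.6"`,
#'   `"SSP2-4.5"`, `"SSP5-8.5"`.
#' @param period Optional period tag (e.g. `"2030s"`, `"2050s"`).
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers, scenario = "near_current", period = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  lapply(layers, function(l) stopifnot(inherits(l, "raster_grid")))
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("layer names must be unique")
  spec <- layers[[1]]$spec
  ok <- vapply(layers, function(l) spec_equal(l$spec, spec), logical(1))
  if (!all(ok))
    stop("alignment error: layers ", paste(nms[!ok], collapse = ", "),
         " do not share the stack's grid_spec")
  names(layers) <- nms
  structure(list(layers = layers, spec = spec, scenario = scenario,
                 period = period),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layer(s) [%s] scenario=%s%s\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$scenario, if (is.null(x$period)) "" else paste0(" period=", x$period)))
  print(x$spec)
  invisible(x)
}

#' Flatten a stack into a cells-by-layers matrix
#'
#' @param stack A [layer_stack()].
#' @return Numeric matrix with one row per grid cell (row-major over the
#'   raster matrix, i.e. cell `(r, c)` at index `(c-1) * n_rows + r`) and
#'   one named column per layer.
#' @export
stack_matrix <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  vapply(stack$layers, function(l) as.vector(l$values),
         numeric(stack$spec$n_rows * stack$spec$n_cols))
}

# ---- file I/O -------------------------------------------------------------

#' Read a geographic raster layer
#'
#' Supported interchange formats are the ESRI ASCII grid (plain text, exact
#' round-trip) and single-band float GeoTIFF (uncompressed IEEE-float
#' samples with a geographic georeference; round-trip within float32
#' precision).
#'
#' @param path File path.
#' @param format `"ascii_grid"` or `"geotiff"`; by default guessed from the
#'   file extension (`.asc` vs `.tif`/`.tiff`).
#' @param name Layer name; defaults to the file's base name.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     asc = "ascii_grid", tif = "geotiff", tiff = "geotiff",
                     stop("cannot guess raster format from extension: ", path))
  }
  format <- match.arg(format, c("ascii_grid", "geotiff"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  switch(format,
         ascii_grid = read_ascii_grid(path, name),
         geotiff = read_geotiff(path, name))
}

#' Write a geographic raster layer
#'
#' @param grid A [raster_grid()].
#' @param path Output path.
#' @param format See [read_raster()].
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = NULL) {
  stopifnot(inherits(grid, "raster_grid"))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     asc = "ascii_grid", tif = "geotiff", tiff = "geotiff",
                     stop("cannot guess raster format from extension: ", path))
  }
  format <- match.arg(format, c("ascii_grid", "geotiff"))
  if (format == "ascii_grid") write_ascii_grid(grid, path)
  else write_geotiff(grid, path)
  invisible(path)
}

read_ascii_grid <- function(path, name) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))))
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("format error: ", path, " lacks an ESRI ASCII grid header")
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy)
    stop("format error: non-square cells are not supported")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_rows <- hdr$nrows; n_cols <- hdr$ncols; cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) west <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) west <- hdr$xllcenter - cs / 2
  else stop("format error: missing x georeference in ", path)
  if (!is.null(hdr$yllcorner)) south <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) south <- hdr$yllcenter - cs / 2
  else stop("format error: missing y georeference in ", path)
  n_header <- sum(vapply(lines, function(ln) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
      tolower(parts[1]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                               "xllcenter", "yllcenter", "cellsize", "dx",
                               "dy", "nodata_value")
  }, logical(1)))
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != n_rows * n_cols)
    stop("format error: expected ", n_rows * n_cols, " values, found ",
         length(vals), " in ", path)
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  spec <- grid_spec(n_rows, n_cols, west = west, north = south + n_rows * cs,
                    cell_deg = cs, nodata = nodata)
  raster_grid(m, spec, name)
}

write_ascii_grid <- function(grid, path) {
  spec <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$west),
    sprintf("yllcorner %.10g", spec$north - spec$n_rows * spec$cell_deg),
    sprintf("cellsize %.10g", spec$cell_deg),
    sprintf("NODATA_value %.10g", spec$nodata)), con)
  m <- grid$values
  m[is.na(m)] <- spec$nodata
  for (r in seq_len(spec$n_rows))
    writeLines(paste(format(m[r, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
}

#' Read a layer stack from a manifest
#'
#' The manifest is a two-column delimited file (`name`, `path`) declaring
#' one raster per line; relative paths are resolved against the manifest's
#' directory.
#'
#' @param manifest Path to the manifest CSV.
#' @param scenario,period Passed to [layer_stack()].
#' @return A [layer_stack()].
#' @export
read_stack <- function(manifest, scenario = "near_current", period = NULL) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("name", "path") %in% names(tab)))
    stop("manifest must have 'name' and 'path' columns")
  base <- dirname(manifest)
  layers <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_raster(p, name = tab$name[i])
  })
  layer_stack(layers, scenario = scenario, period = period)
}

# ---- point extraction -----------------------------------------------------

#' Locate points on a grid
#'
#' Maps longitude/latitude points to cell (row, col) indices under the
#' half-open cell convention `[west, east)` x `(south, north]`.
#'
#' @param spec A [grid_spec()].
#' @param lon,lat Numeric vectors of coordinates.
#' @return Integer matrix with columns `row`, `col`; `NA` rows for points
#'   outside the grid.
#' @export
locate_cells <- function(spec, lon, lat) {
  stopifnot(inherits(spec, "grid_spec"), length(lon) == length(lat))
  col <- floor((lon - spec$west) / spec$cell_deg) + 1
  row <- floor((spec$north - lat) / spec$cell_deg) + 1
  # north edge of the grid belongs to the top row ((south, north] closed top)
  row[lat == spec$north] <- 1
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract covariate values at occurrence points
#'
#' @param stack A [layer_stack()].
#' @param points An occurrence table (see [load_occurrences()]) or any
#'   data frame with `longitude` and `latitude` columns.
#' @return A list with `values` (points x layers matrix), `in_bounds`
#'   (logical: point fell on a data cell in every layer), and `n_masked`.
#'   Rows of `values` for masked points are `NA`.
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(inherits(stack, "layer_stack"))
  lon <- points$longitude; lat <- points$latitude
  rc <- locate_cells(stack$spec, lon, lat)
  X <- matrix(NA_real_, nrow = length(lon), ncol = length(stack$layers),
              dimnames = list(NULL, names(stack$layers)))
  inside <- !is.na(rc[, "row"])
  if (any(inside)) {
    idx <- cbind(rc[inside, "row"], rc[inside, "col"])
    for (j in seq_along(stack$layers))
      X[inside, j] <- stack$layers[[j]]$values[idx]
  }
  ok <- inside & rowSums(is.na(X)) == 0L
  X[!ok, ] <- NA_real_
  list(values = X, in_bounds = ok, n_masked = sum(!ok))
}
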