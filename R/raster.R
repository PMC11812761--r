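#' Georeferenced raster grid
#'
#' A light container for the single-band rasters the model works with:
#' population density, road friction, travel time, probability and
#' lives-saved surfaces. The grid is north-up: row 1 is the top (northern)
#' row and cell values refer to the cell centre. Coordinates are planar map
#' units in metres; exact geodesy is out of scope and users of
#' geographic-CRS rasters can override the cell area where it matters (see
#' [cell_area_km2()]).
#'
#' @param values Numeric matrix; `NA` marks nodata cells.
#' @param xmin,ymax Map coordinates (metres) of the grid's top-left corner.
#' @param xres,yres Cell width and height in metres; must be positive.
#' @param units Free-text unit tag, e.g. `"persons/km2"`, `"min/m"`,
#'   `"minutes"`, `"probability"`, `"lives"`.
#' @param nodata Sentinel value used when the grid is written to file.
#'
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(runif(25), 5, 5), xres = 1000, yres = 1000,
#'                  units = "persons/km2")
#' cell_area_km2(g)
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values) * yres,
                        xres = 1000, yres = xres, units = "",
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(xres > 0, yres > 0)
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         xres = xres, yres = yres, units = units, nodata = nodata),
    class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid: %d x %d cells (%.3g x %.3g km), units '%s'\n",
              nrow(x$values), ncol(x$values), x$xres / 1000, x$yres / 1000,
              x$units))
  if (length(v)) {
    cat(sprintf("  valid cells: %d; range [%.4g, %.4g]\n",
                length(v), min(v), max(v)))
  } else {
    cat("  no valid cells\n")
  }
  invisible(x)
}

#' @param x A `raster_grid`.
#' @param ... Passed on to [graphics::image()].
#' @rdname raster_grid
#' @export
plot.raster_grid <- function(x, ...) {
  # image() draws row 1 at the bottom; flip so north stays up
  m <- t(x$values[rev(seq_len(nrow(x$values))), , drop = FALSE])
  xs <- x$xmin + (seq_len(ncol(x$values)) - 0.5) * x$xres
  ys <- x$ymax - (rev(seq_len(nrow(x$values))) - 0.5) * x$yres
  graphics::image(xs, ys, m, xlab = "x (m)", ylab = "y (m)",
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Cell geometry helpers
#'
#' `cell_size_km()` returns the cell width and height in kilometres;
#' `cell_area_km2()` the per-cell area used in all population integrals.
#' For rasters in a geographic CRS (degrees) the transform-derived area is
#' meaningless, so an explicit override is accepted everywhere an area is
#' consumed.
#'
#' @param grid A [raster_grid()].
#' @param override Optional explicit cell area in square kilometres.
#' @return A numeric scalar (or length-2 vector for `cell_size_km`).
#' @export
cell_area_km2 <- function(grid, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override > 0)
    return(override)
  }
  (grid$xres / 1000) * (grid$yres / 1000)
}

#' @rdname cell_area_km2
#' @export
cell_size_km <- function(grid) c(width = grid$xres / 1000, height = grid$yres / 1000)

.check_units <- function(grid, units) {
  v <- grid$values
  ok <- switch(units,
    "persons/km2" = all(v >= 0, na.rm = TRUE),
    "min/m" = all(v > 0, na.rm = TRUE),
    "minutes" = all(v >= 0, na.rm = TRUE),
    "probability" = all(v >= 0 & v <= 1, na.rm = TRUE),
    TRUE)
  if (!ok) stop("raster values violate the '", units, "' contract", call. = FALSE)
  invisible(grid)
}

#' Read a single-band GeoTIFF raster
#'
#' Reads an uncompressed single-band GeoTIFF into a [raster_grid()],
#' flagging nodata cells as `NA` and validating the value range implied by
#' `expected_units` (density and travel time non-negative, friction
#' strictly positive, probabilities in \[0, 1\]).
#'
#' @param path Path to a single-band GeoTIFF.
#' @param expected_units Unit tag recorded on the returned grid and used
#'   for range validation.
#' @param quiet Suppress the valid-cell summary message.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, expected_units = "", quiet = FALSE) {
  raw <- read_geotiff(path)
  g <- raster_grid(raw$values, xmin = raw$xmin, ymax = raw$ymax,
                   xres = raw$xres, yres = raw$yres, units = expected_units,
                   nodata = if (is.na(raw$nodata)) -9999 else raw$nodata)
  .check_units(g, expected_units)
  if (!quiet) {
    v <- g$values[!is.na(g$values)]
    message(sprintf("read %s: %d valid cells, range [%.6g, %.6g]",
                    basename(path), length(v),
                    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  }
  g
}

#' Write a raster grid to GeoTIFF
#'
#' Writes an uncompressed single-band GeoTIFF (float32 by default; float64
#' on request). Values, transform and nodata cells round-trip through
#' [read_raster()] exactly (bit-exact at float32 precision).
#'
#' @param grid A [raster_grid()].
#' @param path Output path.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, datatype = c("float32", "float64")) {
  stopifnot(inherits(grid, "raster_grid"))
  datatype <- match.arg(datatype)
  if (any(grid$values == grid$nodata, na.rm = TRUE))
    stop("grid contains cells equal to its nodata sentinel (", grid$nodata, ")")
  write_geotiff(grid$values, path, xmin = grid$xmin, ymax = grid$ymax,
                xres = grid$xres, yres = grid$yres, nodata = grid$nodata,
                datatype = datatype)
  invisible(path)
}

#' Write a PNG quick-look of a raster
#'
#' @param grid A [raster_grid()].
#' @param path Output PNG path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
write_quicklook <- function(grid, path, main = grid$units) {
  grDevices::png(path, width = 720, height = 720)
  on.exit(grDevices::dev.off())
  plot(grid, main = main)
  invisible(path)
}

#' Check that rasters share one grid geometry
#'
#' All rasters entering one model run must live on the same grid. Passes
#' iff every grid matches the first in shape, origin and cell size to
#' within `tol`; otherwise stops, naming the first offending grid.
#'
#' @param grids A list of [raster_grid()] objects (length >= 2).
#' @param tol Numeric tolerance on origin and cell size (map units).
#' @return Invisibly `TRUE` on success.
#' @export
assert_aligned <- function(grids, tol = 1e-9) {
  stopifnot(is.list(grids), length(grids) >= 2)
  nm <- names(grids)
  if (is.null(nm)) nm <- paste0("grid", seq_along(grids))
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    g <- grids[[i]]
    if (!identical(dim(g$values), dim(ref$values)))
      stop("raster '", nm[i], "' is misaligned: shape ",
           paste(dim(g$values), collapse = "x"), " vs ",
           paste(dim(ref$values), collapse = "x"), call. = FALSE)
    geo <- abs(c(g$xmin - ref$xmin, g$ymax - ref$ymax,
                 g$xres - ref$xres, g$yres - ref$yres))
    if (any(geo > tol))
      stop("raster '", nm[i], "' is misaligned: transform differs from '",
           nm[1], "' by more than ", tol, call. = FALSE)
  }
  invisible(TRUE)
}

#' Emergency-capable facility locations
#'
#' Facilities are the sources of the least-cost travel-time computation:
#' the hospitals or clinics an ambulance service would dispatch from.
#' Coordinates are in the same planar map units as the rasters.
#'
#' @param names Character vector of facility names.
#' @param x,y Numeric map coordinates (metres).
#' @return A data.frame of class `facility_set` with columns
#'   `name`, `x`, `y`.
#' @export
facility_set <- function(names, x, y) {
  stopifnot(length(names) == length(x), length(x) == length(y),
            length(x) >= 1)
  structure(data.frame(name = as.character(names), x = as.numeric(x),
                       y = as.numeric(y), stringsAsFactors = FALSE),
            class = c("facility_set", "data.frame"))
}

#' Read facilities from CSV
#'
#' Expects a header `name,lon,lat`; `lon`/`lat` are interpreted as the
#' rasters' planar map coordinates (the pipeline is CRS-agnostic).
#'
#' @param path CSV path.
#' @return A [facility_set()].
#' @export
read_facilities <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "lon", "lat") %in% names(d)))
    stop("facility CSV must have header 'name,lon,lat'")
  facility_set(d$name, d$lon, d$lat)
}

#' @param facilities A [facility_set()].
#' @param path Output CSV path.
#' @rdname read_facilities
#' @export
write_facilities <- function(facilities, path) {
  utils::write.csv(
    data.frame(name = facilities$name, lon = facilities$x, lat = facilities$y),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Snap facilities to the nearest cell centre; returns the input with
# integer row/col columns attached. Errors if any facility falls outside
# the grid.
snap_facilities <- function(facilities, grid) {
  col <- round((facilities$x - grid$xmin) / grid$xres + 0.5)
  row <- round((grid$ymax - facilities$y) / grid$yres + 0.5)
  bad <- row < 1 | row > nrow(grid$values) | col < 1 | col > ncol(grid$values)
  if (any(bad))
    stop("facility outside raster extent: ",
         paste(facilities$name[bad], collapse = ", "))
  facilities$row <- as.integer(row)
  facilities$col <- as.integer(col)
  facilities
}

# Map coordinates of a cell centre.
cell_centre <- function(grid, row, col) {
  cbind(x = grid$xmin + (col - 0.5) * grid$xres,
        y = grid$ymax - (row - 0.5) * grid$yres)
}
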