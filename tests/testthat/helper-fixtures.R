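# Shared fixture builders. Everything is generated in code; no files.

# Random friction grid with an optional fraction of impassable cells.
random_friction <- function(nr = 4, nc = 4, seed = 1, nodata_frac = 0,
                            res_m = 1000) {
  set.seed(seed)
  v <- matrix(stats::runif(nr * nc, 0.001, 0.05), nr, nc)
  if (nodata_frac > 0) {
    drop <- sample(seq_along(v), floor(nodata_frac * length(v)))
    v[drop] <- NA
  }
  raster_grid(v, xres = res_m, yres = res_m, units = "min/m")
}

# A facility at a given (row, col) of a grid, snapped.
facility_at <- function(grid, row, col, name = "f") {
  ctr <- ambusim:::cell_centre(grid, row, col)
  fac <- facility_set(name, ctr[, "x"], ctr[, "y"])
  fac$row <- as.integer(row)
  fac$col <- as.integer(col)
  fac
}

# One-cell travel-time and density grids for single-cell estimator checks.
single_cell <- function(t = 20, rho = 137) {
  list(tt = raster_grid(matrix(t, 1, 1), xres = 1000, units = "minutes"),
       density = raster_grid(matrix(rho, 1, 1), xres = 1000,
                             units = "persons/km2"))
}

# Small synthetic region reused across estimator tests.
small_region <- function(seed = 7, shape = c(25, 25)) {
  spec <- synthetic_spec(shape = shape, n_towns = 3, n_roads = 3,
                         n_facilities = 2, seed = seed)
  reg <- generate_region(spec)
  reg$travel_time <- least_cost_travel_time(reg$friction, reg$facilities,
                                            quiet = TRUE)
  reg
}
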