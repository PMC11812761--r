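#' Specification for a synthetic study region
#'
#' Describes the synthetic inputs the generator emits: a population-density
#' raster made of Gaussian "towns" on a low-density background, a friction
#' raster in which low-friction road corridors cross high-friction terrain,
#' and a set of emergency facilities placed in the largest towns (real
#' regions show the same structure: population clusters around the
#' hospitals, and hospitals sit on the road network).
#'
#' Default friction values correspond to roughly 60 km/h on roads
#' (0.001 min/m) and 5 km/h walking speed off-road (0.012 min/m), the
#' scale used by global motorised-friction surfaces.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param cell_km Cell size in km (square cells).
#' @param n_towns Number of Gaussian population clusters.
#' @param town_peak_density Peak density added by one town (persons/km2).
#' @param background_density Background density (persons/km2).
#' @param town_sd_km Standard deviation of the town kernel (km).
#' @param n_roads Number of road corridors between town centres.
#' @param road_friction_min_per_m Friction on road cells (minutes/metre).
#' @param offroad_friction_min_per_m Friction off-road; must exceed the
#'   road friction (roads are faster).
#' @param n_facilities Number of emergency facilities (placed at the
#'   densest town centres); must not exceed `n_towns`.
#' @param seed Integer seed; every generated artefact is deterministic
#'   given the seed (R's default Mersenne-Twister stream).
#' @return An object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(shape = c(40, 40), n_towns = 4, seed = 1)
#' d <- generate_density(spec)
#' @export
synthetic_spec <- function(shape = c(50, 50), cell_km = 1, n_towns = 5,
                           town_peak_density = 1000, background_density = 5,
                           town_sd_km = 3, n_roads = 6,
                           road_friction_min_per_m = 0.001,
                           offroad_friction_min_per_m = 0.012,
                           n_facilities = 4, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 1), cell_km > 0,
            n_towns >= 0, town_peak_density > 0, background_density >= 0,
            town_sd_km > 0, n_roads >= 0,
            road_friction_min_per_m > 0,
            offroad_friction_min_per_m > road_friction_min_per_m,
            n_facilities >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Town centres drawn from their own seeded stream so each artefact is
# reproducible in isolation.
.town_centres <- function(spec) {
  set.seed(spec$seed)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  data.frame(row = sample.int(nr, spec$n_towns, replace = TRUE),
             col = sample.int(nc, spec$n_towns, replace = TRUE))
}

#' Generate a synthetic population-density raster
#'
#' Density is `background + sum of Gaussian town kernels`, each kernel
#' peaking at `town_peak_density` with standard deviation `town_sd_km` and
#' truncated at four standard deviations (negligible mass beyond). Town
#' centres are uniform over the grid, deterministic given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [raster_grid()] with units `"persons/km2"`.
#' @export
generate_density <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  res_m <- spec$cell_km * 1000
  values <- matrix(spec$background_density, nr, nc)
  if (spec$n_towns > 0) {
    towns <- .town_centres(spec)
    sd_cells <- spec$town_sd_km / spec$cell_km
    trunc_cells <- ceiling(4 * sd_cells)
    for (k in seq_len(spec$n_towns)) {
      r0 <- towns$row[k]; c0 <- towns$col[k]
      rr <- max(1, r0 - trunc_cells):min(nr, r0 + trunc_cells)
      cc <- max(1, c0 - trunc_cells):min(nc, c0 + trunc_cells)
      d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
      kern <- spec$town_peak_density * exp(-d2 / (2 * sd_cells^2))
      kern[sqrt(d2) > 4 * sd_cells] <- 0
      values[rr, cc] <- values[rr, cc] + kern
    }
  }
  raster_grid(values, xres = res_m, yres = res_m, units = "persons/km2")
}

# Bresenham-style raster line between two cells (inclusive).
.raster_line <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  cbind(row = round(seq(r0, r1, length.out = n)),
        col = round(seq(c0, c1, length.out = n)))
}

#' Generate a synthetic friction raster and facility set
#'
#' Roads are straight low-friction corridors chaining the town centres
#' (densest first), so facilities always sit on the road network;
#' remaining cells get the off-road friction. Facilities are placed at the
#' `n_facilities` town centres with the highest realised density,
#' mirroring regions where hospitals sit in the major towns.
#'
#' @param spec A [synthetic_spec()]; must be the spec `density` was
#'   generated from.
#' @param density The [raster_grid()] returned by [generate_density()].
#' @return A list with elements `friction` (a [raster_grid()], units
#'   `"min/m"`) and `facilities` (a [facility_set()] with snapped
#'   `row`/`col`).
#' @export
generate_friction_and_facilities <- function(spec, density) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(density, "raster_grid"))
  if (spec$n_facilities > spec$n_towns)
    stop("n_facilities (", spec$n_facilities, ") exceeds n_towns (",
         spec$n_towns, ")")
  nr <- spec$shape[1]; nc <- spec$shape[2]
  towns <- .town_centres(spec)
  dens_at <- density$values[cbind(towns$row, towns$col)]
  ord <- order(dens_at, decreasing = TRUE)
  towns <- towns[ord, , drop = FALSE]

  values <- matrix(spec$offroad_friction_min_per_m, nr, nc)
  set.seed(spec$seed + 1L)   # road stream, independent of town placement
  n_chain <- min(spec$n_roads, nrow(towns) - 1L)
  if (n_chain > 0) {
    for (k in seq_len(n_chain)) {
      line <- .raster_line(towns$row[k], towns$col[k],
                           towns$row[k + 1L], towns$col[k + 1L])
      values[line] <- spec$road_friction_min_per_m
    }
  }
  n_extra <- spec$n_roads - n_chain
  if (n_extra > 0 && nrow(towns) >= 2) {
    for (k in seq_len(n_extra)) {
      ij <- sample.int(nrow(towns), 2L)
      line <- .raster_line(towns$row[ij[1]], towns$col[ij[1]],
                           towns$row[ij[2]], towns$col[ij[2]])
      values[line] <- spec$road_friction_min_per_m
    }
  }

  fac_idx <- seq_len(spec$n_facilities)
  if (spec$n_roads > 0) {
    # a hospital sits on a road: its own cell is a road cell
    values[cbind(towns$row[fac_idx], towns$col[fac_idx])] <-
      spec$road_friction_min_per_m
  }
  friction <- raster_grid(values, xres = spec$cell_km * 1000,
                          yres = spec$cell_km * 1000, units = "min/m")
  ctr <- cell_centre(friction, towns$row[fac_idx], towns$col[fac_idx])
  fac <- facility_set(sprintf("facility_%d", fac_idx), ctr[, "x"], ctr[, "y"])
  fac$row <- towns$row[fac_idx]
  fac$col <- towns$col[fac_idx]
  list(friction = friction, facilities = fac)
}

#' Generate the full synthetic input set
#'
#' Convenience wrapper returning aligned density and friction rasters plus
#' the facility set for one [synthetic_spec()].
#'
#' @param spec A [synthetic_spec()].
#' @return A list `density`, `friction`, `facilities`.
#' @export
generate_region <- function(spec) {
  density <- generate_density(spec)
  ff <- generate_friction_and_facilities(spec, density)
  list(density = density, friction = ff$friction, facilities = ff$facilities)
}

#' Tiny hand-checkable fixture
#'
#' A 5x5 region with 1 km cells, uniform friction 0.02 min/m, density 100
#' persons/km2 everywhere and a single facility at the centre cell.
#' Travel times from the facility are hand-computable: 20 min to an
#' orthogonal neighbour (1000 m x 0.02 min/m), 28.28 min to a diagonal
#' one (1000*sqrt(2) m x 0.02 min/m).
#'
#' @return A list `density`, `friction`, `facilities`.
#' @export
tiny_fixture <- function() {
  res_m <- 1000
  density <- raster_grid(matrix(100, 5, 5), xres = res_m, yres = res_m,
                         units = "persons/km2")
  friction <- raster_grid(matrix(0.02, 5, 5), xres = res_m, yres = res_m,
                          units = "min/m")
  ctr <- cell_centre(friction, 3L, 3L)
  fac <- facility_set("centre", ctr[, "x"], ctr[, "y"])
  fac$row <- 3L
  fac$col <- 3L
  list(density = density, friction = friction, facilities = fac)
}
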