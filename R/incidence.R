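# Incidence model: expected annual severe cases per cell. Incidence is a
# Gamma-distributed percentage of live births (shape 2, scale 0.5 by
# default, mode 0.5% of live births); live births come from the density
# raster via a crude birth rate.

#' Mode of the Gamma incidence distribution
#'
#' For shape > 1 the Gamma mode is `(shape - 1) * scale`, in percent of
#' live births. The default (2, 0.5) puts the most likely incidence at
#' 0.5% of live births.
#'
#' @param gamma_shape Shape parameter; must exceed 1 for the mode to be
#'   positive.
#' @param gamma_scale Scale parameter; > 0.
#' @return Mode in percent of live births.
#' @examples
#' incidence_mode(2, 0.5)  # 0.5
#' @export
incidence_mode <- function(gamma_shape = 2, gamma_scale = 0.5) {
  if (gamma_shape <= 1) stop("gamma_shape must exceed 1")
  stopifnot(gamma_scale > 0)
  (gamma_shape - 1) * gamma_scale
}

#' Draw an incidence fraction
#'
#' One Gamma(shape, scale) draw, interpreted as a percentage of live
#' births and divided by 100 to give a fraction.
#'
#' @inheritParams incidence_mode
#' @param n Number of draws.
#' @return Incidence as a positive fraction of live births.
#' @export
sample_incidence <- function(gamma_shape = 2, gamma_scale = 0.5, n = 1) {
  stopifnot(gamma_shape > 0, gamma_scale > 0)
  stats::rgamma(n, shape = gamma_shape, scale = gamma_scale) / 100
}

#' Expected annual severe cases per cell
#'
#' `cases = rho * cell_area_km2 * (birth_rate / 1000) * incidence`:
#' population in the cell, times the crude birth rate, times the incidence
#' fraction of live births. Cases are expected (fractional) counts;
#' no Poisson rounding is applied.
#'
#' @param density Population-density [raster_grid()] (persons/km2).
#' @param incidence_fraction Incidence as a fraction of live births.
#' @param birth_rate_per_1000 Crude birth rate, births per 1000 people per
#'   year (default 27.5).
#' @param area_km2 Optional override of the per-cell area (for
#'   geographic-CRS rasters).
#' @return A [raster_grid()] with units `"cases/year"`.
#' @examples
#' g <- raster_grid(matrix(1000, 1, 1), xres = 1000, units = "persons/km2")
#' as.matrix(cases_per_cell(g, 0.005))  # 0.1375 cases/year
#' @export
cases_per_cell <- function(density, incidence_fraction,
                           birth_rate_per_1000 = 27.5, area_km2 = NULL) {
  stopifnot(inherits(density, "raster_grid"), incidence_fraction >= 0,
            birth_rate_per_1000 >= 0)
  area <- cell_area_km2(density, area_km2)
  v <- density$values * area * (birth_rate_per_1000 / 1000) * incidence_fraction
  raster_grid(v, xmin = density$xmin, ymax = density$ymax,
              xres = density$xres, yres = density$yres, units = "cases/year")
}
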