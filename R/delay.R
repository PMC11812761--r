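# Rayleigh model of the "waiting delay" tau(x): the time spent locating a
# vehicle and driver for informal transport. The delay shrinks with local
# population density (more people, more vehicles nearby): its mean is
# beta / sqrt(rho), so beta is the mean waiting delay where the density is
# one person per km2. The sqrt arises from nearest-vehicle distance in a
# planar Poisson field of vehicles with intensity proportional to rho,
# which also gives tau its Rayleigh shape.

#' Expected waiting delay for informal transport
#'
#' Mean of the Rayleigh waiting-delay distribution at population density
#' `rho`: `beta / sqrt(rho)` minutes. At `rho = 1` the mean is `beta`
#' itself. At the reference density of 137 persons/km2, `beta` of 60, 120,
#' 180, 240 and 300 minutes gives mean delays of 5.1, 10.3, 15.4, 20.5
#' and 25.6 minutes.
#'
#' @param beta Mean waiting delay (minutes) at density 1 person/km2; > 0.
#' @param rho Population density (persons/km2); > 0 (zero-density cells
#'   carry no population and are excluded upstream).
#' @return Expected delay in minutes.
#' @examples
#' expected_delay(60, 137)   # about 5.1 minutes
#' @export
expected_delay <- function(beta, rho) {
  stopifnot(all(beta > 0))
  if (any(rho <= 0)) stop("rho must be positive (zero-density cells are excluded upstream)")
  beta / sqrt(rho)
}

#' Rayleigh scale of the waiting-delay distribution
#'
#' The scale sigma such that a Rayleigh(sigma) variable has mean
#' `beta / sqrt(rho)`; since a Rayleigh mean is `sigma * sqrt(pi / 2)`,
#' `sigma = (beta / sqrt(rho)) * sqrt(2 / pi)`.
#'
#' @inheritParams expected_delay
#' @return Scale parameter in minutes.
#' @export
rayleigh_scale <- function(beta, rho) {
  expected_delay(beta, rho) * sqrt(2 / pi)
}

#' Sample waiting delays
#'
#' Draws from the Rayleigh waiting-delay distribution via inversion
#' (`sigma * sqrt(-2 log U)`), vectorised over `rho`.
#'
#' @inheritParams expected_delay
#' @param n Number of draws; defaults to `length(rho)` so one draw per
#'   density value.
#' @return Non-negative delays in minutes.
#' @export
sample_delay <- function(beta, rho, n = length(rho)) {
  sigma <- rayleigh_scale(beta, rho)
  sigma * sqrt(-2 * log(stats::runif(n)))
}

#' Probability the ambulance beats informal transport
#'
#' The ambulance (round trip from a facility-based hub) takes `2*s*t`
#' minutes against `t + tau` for informal transport, so the ambulance is
#' faster exactly when `tau > (2*s - 1) * t`. Under the Rayleigh delay
#' model this probability is the Rayleigh survival function at the
#' threshold: 1 when `(2s - 1) t <= 0` (in particular whenever
#' `s <= 0.5`), else `exp(-((2s-1)t)^2 / (2 sigma^2))`. Unreachable cells
#' (`t = Inf`) get 0: no mode of transport helps there.
#'
#' @param t One-way travel time to the facility (minutes); >= 0, may be
#'   `Inf`.
#' @param rho Population density (persons/km2); > 0.
#' @param beta Waiting-delay parameter (minutes at density 1).
#' @param s Ambulance speed multiplier in (0, 1].
#' @return Probability in \[0, 1\]. Vectorised over all arguments.
#' @examples
#' prob_ambulance_faster(t = 20, rho = 137, beta = 60, s = 0.9)
#' @export
prob_ambulance_faster <- function(t, rho, beta, s) {
  stopifnot(all(t >= 0), all(s > 0), all(s <= 1))
  sigma <- rayleigh_scale(beta, rho)
  thr <- (2 * s - 1) * t
  q <- ifelse(thr <= 0, 1, exp(-thr^2 / (2 * sigma^2)))
  q[is.infinite(t)] <- 0
  q
}

#' Map the probability of improved transfer times
#'
#' Applies [prob_ambulance_faster()] cell-wise to a travel-time surface
#' and density raster. Cells with nodata or zero density (no one to pick
#' up) are nodata in the result.
#'
#' @param t_surface Travel-time [raster_grid()] (units `"minutes"`).
#' @param density Population-density [raster_grid()] (units
#'   `"persons/km2"`), aligned with `t_surface`.
#' @inheritParams prob_ambulance_faster
#' @return A [raster_grid()] with units `"probability"`.
#' @export
q_map <- function(t_surface, density, beta, s) {
  assert_aligned(list(travel_time = t_surface, density = density))
  t <- t_surface$values
  rho <- density$values
  valid <- !is.na(t) & !is.na(rho) & rho > 0
  q <- matrix(NA_real_, nrow(t), ncol(t))
  q[valid] <- prob_ambulance_faster(t[valid], rho[valid], beta, s)
  raster_grid(q, xmin = t_surface$xmin, ymax = t_surface$ymax,
              xres = t_surface$xres, yres = t_surface$yres,
              units = "probability")
}
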