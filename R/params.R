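#' Model parameter bundle
#'
#' Collects every scalar and distributional parameter of the
#' spatial-epidemiological model. Defaults are the applied-example
#' choices: exponential survival rate 0.056/min, Gamma(2, 0.5) incidence
#' (percent of live births), crude birth rate 27.5/1000, full care-seeking
#' with and without the service (p0 = p1 = 1) and zero ambulance call-out
#' delay.
#'
#' @param beta Waiting-delay parameter: mean delay in minutes at density
#'   1 person/km2; > 0.
#' @param s Ambulance speed multiplier in (0, 1].
#' @param lambda_mean,lambda_sd Normal distribution of the survival rate
#'   lambda (per minute), truncated to positive values.
#' @param gamma_shape,gamma_scale Gamma incidence distribution (draws are
#'   percent of live births).
#' @param birth_rate_per_1000 Crude birth rate per 1000 population per
#'   year.
#' @param incidence_fixed Optional fixed incidence fraction; when set, no
#'   Gamma draw is made (used for deterministic checks).
#' @param p0,p1 Care-seeking proportions without / with the service.
#' @param theta Ambulance call-out delay in minutes (default 0, the
#'   model's simplifying assumption).
#' @param cell_area_km2 Optional per-cell area override for
#'   geographic-CRS rasters.
#' @param tau_mode `"sample"` draws one waiting delay per populated cell
#'   per replication; `"expectation"` replaces the draw with the exact
#'   expectation over the Rayleigh delay (variance reduction).
#' @return An object of class `model_params`.
#' @export
model_params <- function(beta = 60, s = 0.9,
                         lambda_mean = 0.056, lambda_sd = 0.01,
                         gamma_shape = 2, gamma_scale = 0.5,
                         birth_rate_per_1000 = 27.5,
                         incidence_fixed = NULL,
                         p0 = 1, p1 = 1, theta = 0,
                         cell_area_km2 = NULL,
                         tau_mode = c("sample", "expectation")) {
  tau_mode <- match.arg(tau_mode)
  stopifnot(beta > 0, s > 0, s <= 1,
            lambda_mean > 0, lambda_sd >= 0,
            gamma_shape > 0, gamma_scale > 0,
            birth_rate_per_1000 >= 0,
            is.null(incidence_fixed) || incidence_fixed >= 0,
            p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1, theta >= 0,
            is.null(cell_area_km2) || cell_area_km2 > 0)
  structure(list(beta = beta, s = s,
                 lambda_mean = lambda_mean, lambda_sd = lambda_sd,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 birth_rate_per_1000 = birth_rate_per_1000,
                 incidence_fixed = incidence_fixed,
                 p0 = p0, p1 = p1, theta = theta,
                 cell_area_km2 = cell_area_km2, tau_mode = tau_mode),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params:\n")
  cat(sprintf("  waiting delay beta = %g min (at density 1/km2); speed multiplier s = %g\n",
              x$beta, x$s))
  cat(sprintf("  survival lambda ~ N(%g, %g)/min (truncated > 0)\n",
              x$lambda_mean, x$lambda_sd))
  if (is.null(x$incidence_fixed)) {
    cat(sprintf("  incidence ~ Gamma(shape %g, scale %g) %% of live births\n",
                x$gamma_shape, x$gamma_scale))
  } else {
    cat(sprintf("  incidence fixed at %g of live births\n", x$incidence_fixed))
  }
  cat(sprintf("  birth rate %g/1000/yr; care-seeking p0 = %g, p1 = %g; theta = %g min\n",
              x$birth_rate_per_1000, x$p0, x$p1, x$theta))
  cat(sprintf("  tau mode: %s\n", x$tau_mode))
  invisible(x)
}
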