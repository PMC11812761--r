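# Monte Carlo estimator of lives saved per year. Each replication draws
# the global parameters (incidence fraction, survival rate lambda) once
# and one Rayleigh waiting delay per populated cell, evaluates survival
# with and without the ambulance service, and sums
#   cases(x) * [p1 * S(t1(x)) - p0 * S(t0(x))]
# over the region. The mean and equal-tailed 95% credible interval come
# from the replication distribution.

# E[exp(-lam * tau)] restricted to tau in [a, b], tau ~ Rayleigh(sigma).
# Closed form by completing the square; used by tau_mode = "expectation".
.rayleigh_laplace <- function(lam, sigma, a = 0, b = Inf) {
  C <- exp(lam^2 * sigma^2 / 2)
  ua <- (a + lam * sigma^2) / sigma
  ub <- (b + lam * sigma^2) / sigma
  ea <- exp(-ua^2 / 2)
  eb <- if (is.infinite(b)) 0 else exp(-ub^2 / 2)
  C * ((ea - eb) - lam * sigma * sqrt(2 * pi) *
         (stats::pnorm(ub) - stats::pnorm(ua)))
}

# Per-cell E[S1] and E[S0] over the Rayleigh delay, vectorised over cells.
.expected_survival_pair <- function(t, sigma, s, lam, scenario, theta = 0) {
  S0 <- exp(-lam * t) * .rayleigh_laplace(lam, sigma)
  S0[is.infinite(t)] <- 0
  S_amb <- survival_prob(lam, t_ambulance(t, s, theta))
  thr <- (2 * s - 1) * t + theta
  S1 <- switch(scenario$choice_rule,
    ambulance = S_amb,
    random = scenario$random_weight * S_amb +
             (1 - scenario$random_weight) * S0,
    fastest = {
      out <- numeric(length(t))
      amb_always <- thr <= 0 | is.infinite(t)
      out[amb_always] <- S_amb[amb_always]
      i <- !amb_always
      if (any(i)) {
        # informal wins while tau <= thr, ambulance beyond
        out[i] <- exp(-lam * t[i]) *
          .rayleigh_laplace(lam, sigma[i], 0, thr[i]) +
          S_amb[i] * exp(-thr[i]^2 / (2 * sigma[i]^2))
      }
      out
    })
  S1[is.infinite(t)] <- 0
  list(S0 = S0, S1 = S1)
}

#' One Monte Carlo replication of the lives-saved estimate
#'
#' Draws one incidence fraction, one survival rate lambda and (in
#' `tau_mode = "sample"`) one Rayleigh waiting delay per populated cell,
#' then evaluates the per-cell lives-saved contribution
#' `cases * (p1 * S1 - p0 * S0)` and its regional sum. Cells with nodata
#' or zero density, or nodata travel time, are excluded; unreachable
#' cells (`t = Inf`) contribute 0 under both scenarios.
#'
#' @param t_surface Travel-time [raster_grid()] (minutes).
#' @param density Population-density [raster_grid()] (persons/km2),
#'   aligned with `t_surface`.
#' @param params A [model_params()].
#' @param scenario A [scenario_spec()].
#' @return A list of class `ems_rep`: `incidence_fraction`, `lam`,
#'   `delta` (lives/year) and `per_cell_delta` (a [raster_grid()], units
#'   `"lives"`).
#' @export
lives_saved_one_rep <- function(t_surface, density, params,
                                scenario = scenario_spec("fastest")) {
  stopifnot(inherits(params, "model_params"),
            inherits(scenario, "scenario_spec"))
  assert_aligned(list(travel_time = t_surface, density = density))
  t <- t_surface$values
  rho <- density$values
  valid <- !is.na(t) & !is.na(rho) & rho > 0

  inc <- if (is.null(params$incidence_fixed)) {
    sample_incidence(params$gamma_shape, params$gamma_scale, 1)
  } else params$incidence_fixed
  lam <- sample_lambda(params$lambda_mean, params$lambda_sd, 1)

  tv <- t[valid]
  rv <- rho[valid]
  if (params$tau_mode == "sample") {
    tau <- sample_delay(params$beta, rv)
    sp <- cell_survival_pair(tv, tau, params$s, lam, scenario, params$theta)
  } else {
    sigma <- rayleigh_scale(params$beta, rv)
    sp <- .expected_survival_pair(tv, sigma, params$s, lam, scenario,
                                  params$theta)
  }
  area <- cell_area_km2(density, params$cell_area_km2)
  cases <- rv * area * (params$birth_rate_per_1000 / 1000) * inc
  dcell <- cases * (params$p1 * sp$S1 - params$p0 * sp$S0)

  per_cell <- matrix(NA_real_, nrow(t), ncol(t))
  per_cell[valid] <- dcell
  structure(
    list(incidence_fraction = inc, lam = lam, delta = sum(dcell),
         per_cell_delta = raster_grid(per_cell, xmin = t_surface$xmin,
                                      ymax = t_surface$ymax,
                                      xres = t_surface$xres,
                                      yres = t_surface$yres,
                                      units = "lives")),
    class = "ems_rep")
}

#' Monte Carlo estimate of lives saved by an ambulance service
#'
#' Replicates the lives-saved integral `n_reps` times, drawing the global
#' parameters (incidence, lambda) once per replication and waiting delays
#' per populated cell, and summarises the replication distribution by its
#' mean and equal-tailed 95% credible interval. Also accumulates the
#' per-cell mean lives-saved map. Identical seed and inputs give
#' bit-identical results.
#'
#' @inheritParams lives_saved_one_rep
#' @param n_reps Number of replications (default 10000).
#' @param seed Optional integer seed; each replication runs on its own
#'   substream derived from it.
#' @param keep_draws Keep the per-replication deltas (default `TRUE`).
#' @return An object of class `ems_sim` with components `mean_delta`,
#'   `cri_low`, `cri_high`, `draws`, `mean_map` (a [raster_grid()]),
#'   `n_reps`, `n_unreachable`, `params`, `scenario`, `seed`.
#' @examples
#' fx <- tiny_fixture()
#' tt <- least_cost_travel_time(fx$friction, fx$facilities)
#' fit <- ems_simulate(tt, fx$density, model_params(beta = 180, s = 0.6),
#'                     scenario_spec("fastest"), n_reps = 200, seed = 1)
#' fit
#' @export
ems_simulate <- function(t_surface, density, params = model_params(),
                         scenario = scenario_spec("fastest"),
                         n_reps = 10000, seed = NULL, keep_draws = TRUE) {
  stopifnot(n_reps >= 1, inherits(params, "model_params"),
            inherits(scenario, "scenario_spec"))
  assert_aligned(list(travel_time = t_surface, density = density))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  # hoisted per-cell state; the replication loop below draws in exactly
  # the same order as lives_saved_one_rep, so both paths agree bit-for-bit
  t <- t_surface$values
  rho <- density$values
  valid <- !is.na(t) & !is.na(rho) & rho > 0
  tv <- t[valid]
  rv <- rho[valid]
  n_valid <- length(tv)
  sigma <- rayleigh_scale(params$beta, rv)
  area <- cell_area_km2(density, params$cell_area_km2)
  cases_per_inc <- rv * area * (params$birth_rate_per_1000 / 1000)
  fixed_lam <- params$lambda_sd == 0
  fixed_inc <- !is.null(params$incidence_fixed)

  draws <- numeric(n_reps)
  sum_cell <- numeric(n_valid)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    inc <- if (fixed_inc) params$incidence_fixed else
      sample_incidence(params$gamma_shape, params$gamma_scale, 1)
    lam <- if (fixed_lam) params$lambda_mean else
      sample_lambda(params$lambda_mean, params$lambda_sd, 1)
    if (params$tau_mode == "sample") {
      tau <- sigma * sqrt(-2 * log(stats::runif(n_valid)))
      sp <- cell_survival_pair(tv, tau, params$s, lam, scenario, params$theta)
    } else {
      sp <- .expected_survival_pair(tv, sigma, params$s, lam, scenario,
                                    params$theta)
    }
    dcell <- cases_per_inc * inc * (params$p1 * sp$S1 - params$p0 * sp$S0)
    draws[r] <- sum(dcell)
    sum_cell <- sum_cell + dcell
  }
  sum_map <- matrix(NA_real_, nrow(t), ncol(t))
  sum_map[valid] <- sum_cell
  ci <- unname(stats::quantile(draws, c(0.025, 0.975), type = 7))
  mean_map <- raster_grid(sum_map / n_reps, xmin = t_surface$xmin,
                          ymax = t_surface$ymax, xres = t_surface$xres,
                          yres = t_surface$yres, units = "lives")
  structure(
    list(mean_delta = mean(draws), cri_low = ci[1], cri_high = ci[2],
         draws = if (keep_draws) draws else NULL,
         mean_map = mean_map, n_reps = n_reps,
         n_unreachable = sum(is.infinite(t_surface$values), na.rm = TRUE),
         params = params, scenario = scenario, seed = seed),
    class = "ems_sim")
}

#' @rdname ems_simulate
#' @export
monte_carlo <- ems_simulate

#' Deterministic single-cell oracle by numerical quadrature
#'
#' For a one-cell domain at fixed lambda and incidence, computes the
#' expected lives-saved contribution by integrating the survival
#' difference against the Rayleigh waiting-delay density with
#' [stats::integrate()]. Independent of the estimator's sampling and
#' closed-form code paths; used to verify them.
#'
#' @param t Scalar one-way travel time (minutes).
#' @param rho Scalar population density (persons/km2).
#' @param params A [model_params()]; `lambda_mean` is used as the fixed
#'   lambda and `incidence_fixed` (or the Gamma mean) as the fixed
#'   incidence.
#' @param scenario A [scenario_spec()].
#' @param area_km2 Cell area (default 1 km2).
#' @return Expected lives saved per year on the single cell.
#' @export
quadrature_oracle <- function(t, rho, params, scenario = scenario_spec("fastest"),
                              area_km2 = 1) {
  if (length(t) != 1 || length(rho) != 1)
    stop("quadrature_oracle is defined for a single cell only")
  stopifnot(inherits(params, "model_params"))
  lam <- params$lambda_mean
  inc <- if (is.null(params$incidence_fixed)) {
    params$gamma_shape * params$gamma_scale / 100
  } else params$incidence_fixed
  sigma <- rayleigh_scale(params$beta, rho)
  fray <- function(tau) tau / sigma^2 * exp(-tau^2 / (2 * sigma^2))
  t1_of_tau <- function(tau) {
    amb <- t_ambulance(t, params$s, params$theta)
    inf <- t_informal(t, tau)
    switch(scenario$choice_rule,
      fastest = pmin(inf, amb),
      ambulance = rep(amb, length(tau)),
      random = NA)  # handled below as a mixture
  }
  # integrate over a finite range holding all the Rayleigh mass to double
  # precision; keeps the quadrature well-conditioned when sigma is tiny
  upper <- sigma * 38
  E_S0 <- stats::integrate(function(tau) survival_prob(lam, t_informal(t, tau)) * fray(tau),
                           0, upper, rel.tol = 1e-10)$value
  if (scenario$choice_rule == "random") {
    w <- scenario$random_weight
    E_S1 <- w * survival_prob(lam, t_ambulance(t, params$s, params$theta)) +
      (1 - w) * E_S0
  } else if (scenario$choice_rule == "fastest") {
    # split the integral at the kink where ambulance overtakes informal
    thr <- (2 * params$s - 1) * t + params$theta
    f <- function(tau) survival_prob(lam, t1_of_tau(tau)) * fray(tau)
    E_S1 <- if (thr > 0 && thr < upper) {
      stats::integrate(f, 0, thr, rel.tol = 1e-10)$value +
        stats::integrate(f, thr, upper, rel.tol = 1e-10)$value
    } else {
      # one mode wins over the whole mass: no kink inside (0, upper)
      stats::integrate(f, 0, upper, rel.tol = 1e-10)$value
    }
  } else {
    E_S1 <- survival_prob(lam, t_ambulance(t, params$s, params$theta))
  }
  cases <- rho * area_km2 * (params$birth_rate_per_1000 / 1000) * inc
  cases * (params$p1 * E_S1 - params$p0 * E_S0)
}

#' Lives saved across a grid of beta and speed values
#'
#' Runs [ems_simulate()] for every (beta, s) combination with common
#' random numbers (the same seed for every combination), giving one row
#' per combination with the mean and 95% credible interval.
#'
#' @inheritParams ems_simulate
#' @param betas Numeric vector of waiting-delay parameters.
#' @param speeds Numeric vector of speed multipliers.
#' @param keep_maps Keep each combination's mean lives-saved map
#'   (attribute `maps`, named `"beta<..>_s<..>"`).
#' @return A data.frame of class `ems_grid` with columns `beta`, `s`,
#'   `mean`, `cri_low`, `cri_high`.
#' @export
results_grid <- function(t_surface, density, params = model_params(),
                         scenario = scenario_spec("fastest"),
                         betas = c(60, 120, 180, 240, 300),
                         speeds = c(0.6, 0.7, 0.8, 0.9),
                         n_reps = 10000, seed = NULL, keep_maps = FALSE) {
  combos <- expand.grid(beta = betas, s = speeds,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(combos))
  maps <- if (keep_maps) vector("list", nrow(combos)) else NULL
  for (i in seq_len(nrow(combos))) {
    p <- params
    p$beta <- combos$beta[i]
    p$s <- combos$s[i]
    fit <- ems_simulate(t_surface, density, p, scenario,
                        n_reps = n_reps, seed = seed, keep_draws = FALSE)
    rows[[i]] <- data.frame(beta = p$beta, s = p$s, mean = fit$mean_delta,
                            cri_low = fit$cri_low, cri_high = fit$cri_high)
    if (keep_maps) {
      maps[[i]] <- fit$mean_map
      names(maps)[i] <- sprintf("beta%g_s%g", p$beta, p$s)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ems_grid", "data.frame")
  attr(out, "n_reps") <- n_reps
  attr(out, "scenario") <- scenario$choice_rule
  if (keep_maps) attr(out, "maps") <- maps
  out
}

#' Write a results grid as a speed-by-beta CSV table
#'
#' Lays the grid out with one row per speed multiplier and one column per
#' beta, each cell `mean (cri_low to cri_high)`.
#'
#' @param grid An `ems_grid` from [results_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_grid <- function(grid, path) {
  betas <- unique(grid$beta)
  speeds <- unique(grid$s)
  tab <- matrix("", length(speeds), length(betas),
                dimnames = list(NULL, paste0("beta_", betas)))
  for (i in seq_along(speeds)) {
    for (j in seq_along(betas)) {
      r <- grid[grid$s == speeds[i] & grid$beta == betas[j], ]
      tab[i, j] <- sprintf("%.1f (%.1f to %.1f)", r$mean, r$cri_low, r$cri_high)
    }
  }
  utils::write.csv(data.frame(s = speeds, tab, check.names = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
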