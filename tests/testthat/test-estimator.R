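test_that("each replication conserves mass: delta equals the map sum", {
  reg <- small_region()
  p <- model_params(beta = 180, s = 0.7)
  for (rule in c("fastest", "ambulance", "random")) {
    set.seed(10)
    rep <- lives_saved_one_rep(reg$travel_time, reg$density, p,
                               scenario_spec(rule))
    expect_equal(rep$delta, sum(as.matrix(rep$per_cell_delta), na.rm = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("degenerate geometry gives zero benefit", {
  # s = 0.5 and beta -> 0: ambulance time equals informal time in the limit
  sc <- single_cell(t = 30, rho = 137)
  p <- model_params(beta = 1e-9, s = 0.5, lambda_sd = 0,
                    incidence_fixed = 0.005)
  set.seed(1)
  rep <- lives_saved_one_rep(sc$tt, sc$density, p, scenario_spec("fastest"))
  expect_equal(rep$delta, 0, tolerance = 1e-10)
  # beta -> 0 with s > 0.5 and fastest rule: informal (no delay) wins, delta = 0
  p2 <- model_params(beta = 1e-9, s = 0.9, lambda_sd = 0,
                     incidence_fixed = 0.005)
  set.seed(1)
  rep2 <- lives_saved_one_rep(sc$tt, sc$density, p2, scenario_spec("fastest"))
  expect_equal(rep2$delta, 0, tolerance = 1e-10)
})

test_that("replication signs: fastest never loses lives, ambulance can", {
  reg <- small_region()
  fitF <- ems_simulate(reg$travel_time, reg$density,
                       model_params(beta = 120, s = 0.8),
                       scenario_spec("fastest"), n_reps = 200, seed = 3)
  expect_true(all(fitF$draws >= 0))
  fitA <- ems_simulate(reg$travel_time, reg$density,
                       model_params(beta = 60, s = 0.9),
                       scenario_spec("ambulance"), n_reps = 200, seed = 3)
  expect_true(any(fitA$draws < 0))
})

test_that("same seed and config reproduce bit-identical results", {
  reg <- small_region()
  p <- model_params(beta = 240, s = 0.6)
  a <- ems_simulate(reg$travel_time, reg$density, p, n_reps = 50, seed = 42)
  b <- ems_simulate(reg$travel_time, reg$density, p, n_reps = 50, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(as.matrix(a$mean_map), as.matrix(b$mean_map))
  c <- ems_simulate(reg$travel_time, reg$density, p, n_reps = 50, seed = 43)
  expect_false(identical(a$draws, c$draws))
  # n_reps = 1 collapses mean and CrI onto the single draw
  one <- ems_simulate(reg$travel_time, reg$density, p, n_reps = 1, seed = 1)
  expect_equal(one$mean_delta, one$draws[1])
  expect_equal(one$cri_low, one$draws[1])
  expect_equal(one$cri_high, one$draws[1])
})

test_that("Monte Carlo agrees with the quadrature oracle on one cell", {
  p <- model_params(beta = 180, s = 0.6, lambda_sd = 0,
                    incidence_fixed = 0.005)
  sc <- single_cell(t = 20, rho = 137)
  for (rule in c("fastest", "ambulance", "random")) {
    scen <- scenario_spec(rule)
    fit <- ems_simulate(sc$tt, sc$density, p, scen, n_reps = 20000, seed = 8)
    orc <- quadrature_oracle(20, 137, p, scen)
    se <- stats::sd(fit$draws) / sqrt(fit$n_reps)
    if (rule == "ambulance") {
      # tau varies only the baseline; still a Monte Carlo comparison
      expect_lt(abs(fit$mean_delta - orc), 3 * se + 1e-12)
    } else {
      expect_lt(abs(fit$mean_delta - orc), 3 * se)
    }
  }
})

test_that("oracle factorises in closed form under the ambulance rule", {
  # E[S(t+tau)] = exp(-lam t) * E[exp(-lam tau)], the Rayleigh Laplace
  # transform; the oracle integrates numerically and must agree
  p <- model_params(beta = 120, s = 0.8, lambda_sd = 0,
                    incidence_fixed = 0.005)
  t <- 35; rho <- 80
  lam <- p$lambda_mean
  sigma <- rayleigh_scale(p$beta, rho)
  laplace <- ambusim:::.rayleigh_laplace(lam, sigma)
  cases <- rho * 1 * (27.5 / 1000) * 0.005
  closed <- cases * (exp(-lam * 2 * p$s * t) - exp(-lam * t) * laplace)
  expect_equal(quadrature_oracle(t, rho, p, scenario_spec("ambulance")),
               closed, tolerance = 1e-8)
  # beta -> 0: tau degenerates at 0 and the oracle hits S(2st) - S(t)
  p0 <- model_params(beta = 1e-6, s = 0.8, lambda_sd = 0,
                     incidence_fixed = 0.005)
  expect_equal(quadrature_oracle(t, rho, p0, scenario_spec("ambulance")),
               cases * (exp(-lam * 2 * 0.8 * t) - exp(-lam * t)),
               tolerance = 1e-6)
})

test_that("expectation tau mode matches the oracle deterministically", {
  p <- model_params(beta = 180, s = 0.6, lambda_sd = 0,
                    incidence_fixed = 0.005, tau_mode = "expectation")
  sc <- single_cell(t = 20, rho = 137)
  for (rule in c("fastest", "ambulance", "random")) {
    scen <- scenario_spec(rule)
    fit <- ems_simulate(sc$tt, sc$density, p, scen, n_reps = 2, seed = 1)
    expect_equal(fit$mean_delta, quadrature_oracle(20, 137, p, scen),
                 tolerance = 1e-7, info = rule)
    expect_equal(fit$cri_low, fit$cri_high)  # no randomness left
  }
})

test_that("scaling density by k scales lives saved by k", {
  # beta scaled by sqrt(k) keeps sigma, hence the tau draws, unchanged
  reg <- small_region()
  k <- 4
  dens_k <- raster_grid(as.matrix(reg$density) * k,
                        xres = reg$density$xres, units = "persons/km2")
  p1 <- model_params(beta = 120, s = 0.7)
  pk <- model_params(beta = 120 * sqrt(k), s = 0.7)
  a <- ems_simulate(reg$travel_time, reg$density, p1, n_reps = 100, seed = 5)
  b <- ems_simulate(reg$travel_time, dens_k, pk, n_reps = 100, seed = 5)
  expect_equal(b$mean_delta, k * a$mean_delta, tolerance = 1e-12)
})

test_that("results grid is ordered, consistent and monotone with CRN", {
  reg <- small_region()
  p <- model_params()
  grid <- results_grid(reg$travel_time, reg$density, p,
                       betas = c(60, 180, 300), speeds = c(0.6, 0.9),
                       n_reps = 100, seed = 17)
  expect_equal(unique(grid$beta), c(60, 180, 300))  # input ordering kept
  expect_true(all(grid$cri_low <= grid$cri_high))
  for (sv in unique(grid$s)) {
    expect_true(all(diff(grid$mean[grid$s == sv]) >= 0))  # up in beta
  }
  for (bv in unique(grid$beta)) {
    expect_true(all(diff(grid$mean[grid$beta == bv]) <= 0))  # down in s
  }
  # a 1x1 grid equals a direct call
  g1 <- results_grid(reg$travel_time, reg$density, p, betas = 120,
                     speeds = 0.8, n_reps = 50, seed = 9)
  p2 <- model_params(beta = 120, s = 0.8)
  direct <- ems_simulate(reg$travel_time, reg$density, p2, n_reps = 50, seed = 9)
  expect_equal(g1$mean, direct$mean_delta)
  expect_equal(g1$cri_low, direct$cri_low)
})

test_that("median always lies inside the credible interval", {
  reg <- small_region()
  fit <- ems_simulate(reg$travel_time, reg$density,
                      model_params(beta = 300, s = 0.6), n_reps = 200, seed = 2)
  med <- stats::median(fit$draws)
  expect_gte(med, fit$cri_low)
  expect_lte(med, fit$cri_high)
  expect_equal(fit$mean_delta, mean(fit$draws))
})

test_that("oracle refuses non-scalar input", {
  p <- model_params()
  expect_error(quadrature_oracle(c(1, 2), 137, p), "single cell")
})
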