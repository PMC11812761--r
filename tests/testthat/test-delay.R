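test_that("expected delay reproduces the reference values at density 137", {
  expect_equal(round(expected_delay(c(60, 120, 180, 240, 300), 137), 1),
               c(5.1, 10.3, 15.4, 20.5, 25.6))
  expect_equal(expected_delay(60, 1), 60)   # beta is the mean at density 1
  expect_equal(expected_delay(300, 1), 300)
  expect_error(expected_delay(60, 0), "positive")
  expect_error(expected_delay(60, -3), "positive")
})

test_that("Rayleigh scale matches the mean identity and monotonicities", {
  # sigma * sqrt(pi/2) recovers the mean exactly
  for (b in c(60, 180)) for (r in c(1, 137, 900)) {
    expect_equal(rayleigh_scale(b, r) * sqrt(pi / 2), expected_delay(b, r))
  }
  expect_equal(rayleigh_scale(60, 1), 60 * sqrt(2 / pi))
  expect_lt(rayleigh_scale(60, 200), rayleigh_scale(60, 100))   # down in rho
  expect_gt(rayleigh_scale(120, 100), rayleigh_scale(60, 100))  # up in beta
})

test_that("sampled delays are non-negative, reproducible, Rayleigh-distributed", {
  set.seed(1)
  x <- sample_delay(60, rep(137, 1e5))
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - expected_delay(60, 137)),
            3 * sd(x) / sqrt(length(x)))
  # Kolmogorov-Smirnov distance against the Rayleigh CDF
  sigma <- rayleigh_scale(60, 137)
  pray <- function(q) 1 - exp(-q^2 / (2 * sigma^2))
  xs <- sort(x)
  n <- length(xs)
  ks <- max(pmax(abs(seq_len(n) / n - pray(xs)),
                 abs((seq_len(n) - 1) / n - pray(xs))))
  expect_lt(ks, 0.01)
  set.seed(99); a <- sample_delay(60, rep(137, 10))
  set.seed(99); b <- sample_delay(60, rep(137, 10))
  expect_identical(a, b)
})

test_that("probability the ambulance wins: limits and closed form", {
  # s <= 0.5: the round trip never exceeds the one-way informal journey
  expect_equal(prob_ambulance_faster(t = c(0, 10, 500), rho = 137,
                                     beta = 60, s = 0.5), c(1, 1, 1))
  expect_equal(prob_ambulance_faster(t = 0, rho = 5, beta = 300, s = 1), 1)
  # closed form at (t=20, rho=137, beta=60, s=0.9)
  sigma <- rayleigh_scale(60, 137)
  q <- prob_ambulance_faster(20, 137, 60, 0.9)
  expect_equal(q, exp(-16^2 / (2 * sigma^2)))
  expect_lt(abs(q - 4.8e-4), 1e-4)
  # unreachable cell: no benefit from either mode
  expect_equal(prob_ambulance_faster(Inf, 137, 60, 0.9), 0)
})

test_that("q matches the empirical exceedance of sampled delays", {
  n <- 1e6
  set.seed(5)
  tau <- sample_delay(60, rep(137, n))
  q_hat <- mean(tau > 16)
  q <- prob_ambulance_faster(20, 137, 60, 0.9)
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(q_hat - q), 3 * se)
})

test_that("q is monotone in t, rho, beta and s", {
  t <- seq(1, 120, by = 7)
  expect_true(all(diff(prob_ambulance_faster(t, 137, 60, 0.9)) <= 0))
  rho <- seq(1, 2000, by = 100)
  expect_true(all(diff(prob_ambulance_faster(30, rho, 60, 0.9)) <= 0))
  beta <- seq(30, 300, by = 30)
  expect_true(all(diff(prob_ambulance_faster(30, 137, beta, 0.9)) >= 0))
  s <- seq(0.51, 1, by = 0.05)
  expect_true(all(diff(prob_ambulance_faster(30, 137, 60, s)) <= 0))
})

test_that("q_map applies the probability cell-wise with nodata handling", {
  tt <- raster_grid(matrix(c(0, 20, 40, Inf), 2, 2), xres = 1000,
                    units = "minutes")
  dens <- raster_grid(matrix(c(137, 137, 0, NA), 2, 2), xres = 1000,
                      units = "persons/km2")
  q <- q_map(tt, dens, beta = 60, s = 0.9)
  m <- as.matrix(q)
  expect_equal(m[1, 1], 1)                                  # t = 0
  expect_equal(m[2, 1], prob_ambulance_faster(20, 137, 60, 0.9))
  expect_true(is.na(m[1, 2]))                               # zero density
  expect_true(is.na(m[2, 2]))                               # nodata density
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))

  # uniform inputs give a constant map
  ttu <- raster_grid(matrix(25, 3, 3), xres = 1000, units = "minutes")
  du <- raster_grid(matrix(200, 3, 3), xres = 1000, units = "persons/km2")
  expect_equal(length(unique(as.vector(as.matrix(q_map(ttu, du, 60, 0.8))))), 1)

  # high-density cells see lower q at equal travel time
  d2 <- raster_grid(matrix(c(10, 1000, 10, 1000, 10, 1000, 10, 1000, 10), 3, 3),
                    xres = 1000, units = "persons/km2")
  qm <- as.matrix(q_map(ttu, d2, 60, 0.9))
  expect_lt(qm[2, 1], qm[1, 1])

  expect_error(q_map(raster_grid(matrix(1, 2, 2), xres = 1000), du, 60, 0.9),
               "misaligned")
})
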