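test_that("Dijkstra agrees with the Bellman-Ford oracle on random grids", {
  for (seed in 1:30) {
    nr <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    fr <- random_friction(nr, nc, seed = seed,
                          nodata_frac = if (seed %% 3 == 0) 0.2 else 0)
    cells <- which(!is.na(as.matrix(fr)), arr.ind = TRUE)
    fac <- facility_at(fr, cells[1, 1], cells[1, 2])
    for (rule in c("mean", "min", "max")) {
      fast <- least_cost_travel_time(fr, fac, edge_cost = rule, quiet = TRUE)
      slow <- brute_force_travel_time(fr, fac, edge_cost = rule)
      expect_equal(as.matrix(fast), as.matrix(slow),
                   info = sprintf("seed %d rule %s", seed, rule))
    }
  }
})

test_that("uniform friction along a corridor gives distance times friction", {
  # 1 x 5 corridor, facility at the left end: cost is cumulative metres x f
  fr <- raster_grid(matrix(0.02, 1, 5), xres = 1000, units = "min/m")
  fac <- facility_at(fr, 1, 1)
  tt <- as.matrix(least_cost_travel_time(fr, fac, quiet = TRUE))
  expect_equal(tt[1, ], (0:4) * 1000 * 0.02)
})

test_that("unreachable cells get +Inf; nodata stays nodata", {
  v <- matrix(0.02, 5, 5)
  v[2, 2:4] <- NA; v[3, 2] <- NA; v[3, 4] <- NA; v[4, 2:4] <- NA
  fr <- raster_grid(v, xres = 1000, units = "min/m")
  fac <- facility_at(fr, 1, 1)
  expect_message(tt <- least_cost_travel_time(fr, fac), "unreachable")
  m <- as.matrix(tt)
  expect_true(is.infinite(m[3, 3]))    # walled-in centre
  expect_true(is.na(m[2, 2]))
  expect_equal(as.matrix(brute_force_travel_time(fr, fac))[3, 3], Inf)
})

test_that("input errors: empty facilities, facility on nodata, big oracle grid", {
  fr <- random_friction(4, 4, seed = 1)
  expect_error(least_cost_travel_time(fr, NULL), "empty")
  v <- as.matrix(fr); v[2, 2] <- NA
  fr2 <- raster_grid(v, xres = 1000, units = "min/m")
  expect_error(least_cost_travel_time(fr2, facility_at(fr2, 2, 2)),
               "impassable")
  expect_error(brute_force_travel_time(random_friction(6, 6), NULL), "5x5")
})

test_that("monotonicity: faster cells and extra facilities never hurt", {
  fr <- random_friction(5, 5, seed = 9)
  fac <- facility_at(fr, 1, 1)
  base <- as.matrix(least_cost_travel_time(fr, fac, quiet = TRUE))
  # lowering any single friction cell never increases any travel time
  for (cell in c(7, 13, 21)) {
    v <- as.matrix(fr)
    v[cell] <- v[cell] / 10
    lower <- raster_grid(v, xres = 1000, units = "min/m")
    expect_true(all(as.matrix(least_cost_travel_time(lower, fac, quiet = TRUE))
                    <= base + 1e-12))
  }
  # adding a facility never increases any travel time
  fac2 <- rbind(fac, facility_at(fr, 4, 5, "g"))
  two <- as.matrix(least_cost_travel_time(fr, fac2, quiet = TRUE))
  expect_true(all(two <= base + 1e-12))
  expect_equal(two[4, 5], 0)
})

test_that("triangle bound holds on every edge", {
  fr <- random_friction(5, 4, seed = 21)
  fac <- facility_at(fr, 3, 2)
  tt <- as.matrix(least_cost_travel_time(fr, fac, quiet = TRUE))
  edges <- ambusim:::.friction_edges(fr, 8L, "mean")
  expect_true(all(tt[edges$to] <= tt[edges$from] + edges$w + 1e-9))
})

test_that("16-connectivity can only shorten paths", {
  fr <- random_friction(5, 5, seed = 4)
  fac <- facility_at(fr, 1, 1)
  t8 <- as.matrix(least_cost_travel_time(fr, fac, connectivity = 8, quiet = TRUE))
  t16 <- as.matrix(least_cost_travel_time(fr, fac, connectivity = 16, quiet = TRUE))
  expect_true(all(t16 <= t8 + 1e-12))
  expect_error(least_cost_travel_time(fr, fac, connectivity = 4), "8 or 16")
})
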