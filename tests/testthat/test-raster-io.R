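test_that("GeoTIFF round-trip preserves values, transform and nodata", {
  f <- withr::local_tempfile(fileext = ".tif")
  m <- matrix(c(137, NA, 2.5, -4, 0, 1e6), 2, 3)
  g <- raster_grid(m, xmin = 12345, ymax = 67890, xres = 927.6, yres = 412.3,
                   units = "minutes")
  # travel-time units forbid negatives; write through the raw codec tag
  g$units <- ""
  write_raster(g, f)
  r <- read_raster(f, quiet = TRUE)
  want <- matrix(ambusim:::float32(m), 2, 3)
  want[is.na(m)] <- NA_real_   # nodata comes back as NA, not a float NaN
  expect_identical(as.matrix(r), want)
  expect_equal(r$xmin, 12345)
  expect_equal(r$ymax, 67890)
  expect_equal(r$xres, 927.6)
  expect_equal(r$yres, 412.3)
  expect_true(is.na(as.matrix(r)[2, 1]))

  # float64 round-trips exactly
  write_raster(g, f, datatype = "float64")
  r64 <- read_raster(f, quiet = TRUE)
  expect_identical(as.matrix(r64), m)

  # a 1-cell raster round-trips its single value
  f1 <- withr::local_tempfile(fileext = ".tif")
  write_raster(raster_grid(matrix(137, 1, 1), xres = 1000), f1)
  expect_equal(as.matrix(read_raster(f1, quiet = TRUE))[1, 1], 137)
})

test_that("codec output matches an independent TIFF reader", {
  skip_if_not_installed("tiff")
  f <- withr::local_tempfile(fileext = ".tif")
  set.seed(42)
  m <- matrix(runif(30, -50, 5000), 5, 6)
  write_raster(raster_grid(m, xres = 1000), f)
  expect_equal(tiff::readTIFF(f), matrix(ambusim:::float32(m), 5, 6))
})

test_that("read_raster validates the unit contract and band count", {
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(raster_grid(matrix(c(-1, 2), 1, 2), xres = 1000), f)
  expect_error(read_raster(f, "persons/km2", quiet = TRUE), "contract")
  expect_error(read_raster(f, "min/m", quiet = TRUE), "contract")
  write_raster(raster_grid(matrix(c(0.3, 0.9), 1, 2), xres = 1000), f)
  expect_silent(g <- read_raster(f, "probability", quiet = TRUE))
  expect_equal(g$units, "probability")
  expect_error(read_raster(withr::local_tempfile(), ""), "not found")
})

test_that("assert_aligned accepts matching grids and names offenders", {
  a <- raster_grid(matrix(0, 50, 50), xres = 1000)
  expect_true(assert_aligned(list(a, a, a)))
  b <- raster_grid(matrix(0, 49, 50), xres = 1000)
  expect_error(assert_aligned(list(density = a, friction = b)),
               "friction.*misaligned")
  shifted <- raster_grid(matrix(0, 50, 50), xmin = 10, xres = 1000)
  expect_error(assert_aligned(list(a = a, b = shifted)), "transform")
  # sub-tolerance jitter passes
  jitter <- raster_grid(matrix(0, 50, 50), xmin = 1e-12, xres = 1000)
  expect_true(assert_aligned(list(a, jitter)))
  expect_error(assert_aligned(list(a)), "length")
})

test_that("cell geometry helpers give positive, consistent areas", {
  g <- raster_grid(matrix(0, 3, 3), xres = 500, yres = 2000)
  expect_equal(cell_area_km2(g), 0.5 * 2)
  expect_equal(unname(cell_size_km(g)), c(0.5, 2))
  expect_equal(cell_area_km2(g, override = 1.21), 1.21)
  expect_error(raster_grid(matrix(0, 2, 2), xres = -1), "xres")
})

test_that("facility CSV round-trips and snapping flags out-of-extent points", {
  f <- withr::local_tempfile(fileext = ".csv")
  fac <- facility_set(c("a", "b"), c(1500, 4500), c(2500, 500))
  write_facilities(fac, f)
  r <- read_facilities(f)
  expect_equal(r$name, c("a", "b"))
  expect_equal(r$x, c(1500, 4500))
  g <- raster_grid(matrix(0, 5, 5), xres = 1000)
  snapped <- ambusim:::snap_facilities(r, g)
  expect_equal(snapped$row, c(3L, 5L))
  expect_equal(snapped$col, c(2L, 5L))
  outside <- facility_set("far", 99999, 0)
  expect_error(ambusim:::snap_facilities(outside, g), "far")
  writeLines("a,b\n1,2", f)
  expect_error(read_facilities(f), "name,lon,lat")
})
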