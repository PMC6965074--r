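test_that("slope tangent is exact on planes and flats", {
  dem <- make_dem(fixture_spec("inclined_plane", 9, 9, gradient = 0.1))
  slp <- slope_tangent(dem)
  expect_equal(unique(round(as.vector(slp$values), 12)), 0.1)
  flat <- raster_grid(matrix(2, 6, 6), 2)
  expect_equal(max(slope_tangent(flat)$values), 0)
})

test_that("slope on a smooth hill peaks on the flank and vanishes at the crest", {
  dem <- make_dem(fixture_spec("gaussian_hill", 41, 41, cell_size = 2,
                               hill_amplitude = 20, hill_width = 20))
  slp <- slope_tangent(dem)
  centre <- c(21, 21)
  expect_lt(slp$values[21, 21], 0.01)
  # analytic max slope of A*exp(-r^2/2w^2) is at r = w, |dz/dr| = A/(w*sqrt(e))
  analytic <- 20 / (20 * sqrt(exp(1)))
  expect_equal(max(slp$values), analytic, tolerance = 0.05)
})

test_that("DTW accumulates slope cost along cardinal and diagonal steps", {
  # 1 x 6 ramp, uniform tangent s, source at the west end
  s <- 0.2; xc <- 2
  slope <- raster_grid(matrix(s, 1, 6), xc)
  src <- raster_grid(matrix(c(1, 0, 0, 0, 0, 0), 1, 6), xc)
  d <- dtw(slope, src)
  expect_equal(d$values[1, ], (0:5) * s * xc)
  # single diagonal step costs s * sqrt(2) * xc
  slope2 <- raster_grid(matrix(s, 2, 2), xc)
  src2 <- raster_grid(matrix(c(1, 0, 0, 0), 2, 2), xc)
  d2 <- dtw(slope2, src2)
  expect_equal(d2$values[2, 2], s * sqrt(2) * xc)
  expect_equal(d2$values[1, 1], 0)  # source cells are zero
})

test_that("DTW equals the exhaustive simple-path oracle on tiny grids", {
  set.seed(23)
  for (i in 1:4) {
    slope_m <- matrix(runif(9, 0, 0.5), 3, 3)
    src_m <- matrix(FALSE, 3, 3); src_m[sample(9, 2)] <- TRUE
    d <- dtw(raster_grid(slope_m, 2), raster_grid(src_m + 0, 2))
    expect_equal(d$values, dtw_enumerate_oracle(slope_m, src_m, 2),
                 tolerance = 1e-12)
  }
  for (i in 1:4) {
    slope_m <- matrix(runif(25, 0, 0.5), 5, 5)
    src_m <- matrix(FALSE, 5, 5); src_m[sample(25, 2)] <- TRUE
    d <- dtw(raster_grid(slope_m, 2), raster_grid(src_m + 0, 2))
    expect_equal(d$values, dtw_relax_oracle(slope_m, src_m, 2),
                 tolerance = 1e-12)
  }
})

test_that("DTW refuses an empty source layer and respects nodata barriers", {
  slope <- raster_grid(matrix(0.1, 4, 4), 2)
  expect_error(dtw(slope, raster_grid(matrix(0, 4, 4), 2)), "empty")
  # a nodata wall isolates the east side
  sl <- matrix(0.1, 3, 5); sl[, 3] <- NA
  src <- matrix(0, 3, 5); src[2, 1] <- 1
  d <- dtw(raster_grid(sl, 2), raster_grid(src, 2))
  expect_true(all(is.na(d$values[, 3:5])))
  expect_false(anyNA(d$values[, 1:2]))
})

test_that("adding sources never increases DTW anywhere", {
  set.seed(29)
  slope_m <- matrix(runif(100, 0, 0.4), 10, 10)
  src1 <- matrix(0, 10, 10); src1[3, 3] <- 1
  src2 <- src1; src2[8, 7] <- 1
  d1 <- dtw(raster_grid(slope_m, 2), raster_grid(src1, 2))
  d2 <- dtw(raster_grid(slope_m, 2), raster_grid(src2, 2))
  expect_true(all(d2$values <= d1$values + 1e-12))
})

test_that("DTW and EAS shrink cellwise as the stream threshold falls", {
  fx <- valley_fixture(41)
  slp <- slope_tangent(fx$cond)
  thresholds <- c(0.05, 0.1, 0.2, 0.4)
  prev_d <- NULL; prev_e <- NULL
  for (thr in thresholds) {
    src <- build_source_layer(extract_streams(fx$acc, thr))
    d <- dtw(slp, src)$values
    e <- eas(fx$dem, fx$ptr, src)$values
    if (!is.null(prev_d)) {
      expect_true(all(prev_d <= d + 1e-12))
      both <- !is.na(prev_e) & !is.na(e)
      expect_true(all(prev_e[both] <= e[both] + 1e-12))
    }
    prev_d <- d; prev_e <- e
  }
})

test_that("EAS measures drop to the first stream cell on the D8 path", {
  # 1 x 6 ramp draining west into a stream at its foot
  z <- matrix(seq(0, 1, length.out = 6), 1, 6)
  g <- raster_grid(z, 2)
  ptr <- d8_pointer(g)
  src <- raster_grid(matrix(c(1, 0, 0, 0, 0, 0), 1, 6), 2)
  e <- eas(g, ptr, src)
  expect_equal(e$values[1, ], z[1, ] - z[1, 1])
  expect_equal(e$values[1, 1], 0)
  expect_error(eas(g, ptr, raster_grid(matrix(0, 1, 6), 2)), "empty")
})

test_that("EAS is non-negative on a conditioned DEM and nodata past the outlet", {
  dem <- make_dem(fixture_spec("composite_landscape", 40, 40, seed = 6))
  cond <- condition_dem(dem)
  ptr <- d8_pointer(cond)
  acc <- d8_accumulation(ptr, units = "cells")
  src <- build_source_layer(extract_streams(acc, 0.02))
  e <- eas(cond, ptr, src)
  expect_true(all(e$values >= -1e-9, na.rm = TRUE))
})

test_that("TWI closed forms and invariances hold", {
  one <- raster_grid(matrix(1, 2, 2), 1)
  expect_equal(twi(one, one)$values[1, 1], 0)              # ln 1
  e_grid <- raster_grid(matrix(exp(1), 2, 2), 1)
  expect_equal(twi(e_grid, one)$values[1, 1], 1)           # ln e
  # slope floor keeps flats finite
  flat_slope <- raster_grid(matrix(0, 2, 2), 1)
  expect_true(all(is.finite(twi(one, flat_slope)$values)))
  # invariant under uniform elevation offset
  dem <- make_dem(fixture_spec("v_valley", 31, 31))
  shifted <- rg <- dem; shifted$values <- dem$values + 100
  t1 <- twi(dinf_sca(condition_dem(dem)), slope_tangent(condition_dem(dem)))
  t2 <- twi(dinf_sca(condition_dem(shifted)),
            slope_tangent(condition_dem(shifted)))
  expect_equal(t1$values, t2$values, tolerance = 1e-9)
  # on a uniform plane TWI increases downslope with catchment area
  plane <- make_dem(fixture_spec("inclined_plane", 12, 12, gradient = 0.1))
  tp <- twi(dinf_sca(condition_dem(plane)), slope_tangent(condition_dem(plane)))
  mid <- tp$values[6, 2:11]
  expect_true(all(diff(rev(mid)) > 0))  # grows towards the west outlet
})

test_that("focal standard deviation matches direct formulas", {
  expect_equal(max(focal_stdv(raster_grid(matrix(4, 9, 9), 2), 5)$values), 0)
  m <- matrix(1:25, 5, 5, byrow = TRUE)
  fs <- focal_stdv(raster_grid(m, 2), 5)
  expect_equal(fs$values[3, 3], sqrt(mean((1:25 - mean(1:25))^2)))
  # on a plane the window sd grows linearly with window size
  plane <- make_dem(fixture_spec("inclined_plane", 100, 100, gradient = 0.1))
  sds <- vapply(c(5, 10, 20, 40), function(w)
    focal_stdv(plane, w)$values[50, 50], 0)
  # population sd of a ramp over w cells is g*cs*sqrt((w^2-1)/12)
  analytic <- 0.1 * 2 * sqrt((c(5, 10, 20, 40)^2 - 1) / 12)
  expect_equal(sds, analytic, tolerance = 1e-9)
})

test_that("even focal windows anchor the extra row/column south-east", {
  m <- matrix(0, 6, 6); m[4, 4] <- 1  # single spike
  fs <- focal_stdv(raster_grid(m, 2), 2)
  # the 2x2 window of cell (3,3) covers rows 3:4, cols 3:4 -> sees the spike
  expect_gt(fs$values[3, 3], 0)
  # the window of cell (4,4) covers rows 4:5, cols 4:5 -> also sees it
  expect_gt(fs$values[4, 4], 0)
  # the window of cell (5,5) covers rows 5:6, cols 5:6 -> does not
  expect_equal(fs$values[5, 5], 0)
})

test_that("the baseline map thresholds DTW at one metre inclusively", {
  d <- raster_grid(matrix(c(0, 0.5, 1.0, 1.01, 2, 10), 2, 3), 2)
  wet <- sfa_baseline_map(d)
  expect_equal(wet$values, (d$values <= 1) + 0)
  expect_equal(wet$values[d$values == 1.0], 1)   # inclusive
  expect_equal(wet$values[d$values == 1.01], 0)
})
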