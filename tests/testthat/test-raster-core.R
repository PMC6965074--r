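test_that("ASCII grid read/write round-trips values, metadata and nodata", {
  v <- matrix(rnorm(12), 3, 4)
  v[2, 3] <- NA
  g <- raster_grid(v, 2, origin_x = 100, origin_y = 250, crs_tag = "local")
  f <- withr::local_tempfile(fileext = ".asc")
  write_raster(g, f)
  r <- read_raster(f, crs_tag = "local")
  expect_identical(r$values[!is.na(v)], v[!is.na(v)])
  expect_true(is.na(r$values[2, 3]))
  expect_equal(r$cell_size, 2)
  expect_equal(r$origin_x, 100)
  expect_equal(r$origin_y, 250)
  # standard header keywords, in order, readable by common GIS
  hdr <- tolower(sub("\\s.*", "", readLines(f, n = 6)))
  expect_identical(hdr, c("ncols", "nrows", "xllcorner", "yllcorner",
                          "cellsize", "nodata_value"))
})

test_that("fixture DEM written to disk re-reads with its geometry intact", {
  dem <- make_dem(fixture_spec("gaussian_hill", 100, 100, cell_size = 2))
  f <- withr::local_tempfile(fileext = ".asc")
  write_raster(dem, f)
  r <- read_raster(f)
  expect_identical(dim(r$values), c(100L, 100L))
  expect_equal(r$cell_size, 2)
  expect_equal(max(abs(r$values - dem$values)), 0)
})

test_that("degenerate raster input is rejected with a named defect", {
  expect_error(read_raster(tempfile()), "does not exist")
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "dx 1", "dy 2", "1 2", "3 4"), f)
  expect_error(read_raster(f), "non-square")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1", "1 2", "3 4"), f)
  expect_error(read_raster(f), "georeference")
  # geographic degrees rejected: metric CRS is required
  writeLines(c("ncols 2", "nrows 2", "xllcorner 17.5", "yllcorner 64.1",
               "cellsize 0.0001", "1 2", "3 4"), f)
  expect_error(read_raster(f), "projected CRS")
  expect_error(read_raster(f <- f, format = "geotiff"), "not supported")
})

test_that("rasterize_polygons follows the cell-centre rule", {
  template <- raster_grid(matrix(0, 4, 4), 1)  # centres at 0.5..3.5
  # square covering exactly the 4 centres (1.5, 2.5) x (1.5, 2.5)
  sq <- matrix(c(1.2, 1.2, 2.8, 1.2, 2.8, 2.8, 1.2, 2.8, 1.2, 1.2),
               ncol = 2, byrow = TRUE)
  out <- rasterize_polygons(list(sq), template)
  expect_equal(sum(out$values), 4)
  expect_equal(out$values[2:3, 2:3], matrix(1, 2, 2))
  # empty set and fully-outside polygon give all-false
  expect_equal(sum(rasterize_polygons(list(), template)$values), 0)
  far <- sq + 100
  expect_equal(sum(rasterize_polygons(list(far), template)$values), 0)
})

test_that("GeoJSON polygons rasterize like coordinate-matrix polygons", {
  template <- raster_grid(matrix(0, 4, 4), 1)
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    geometry = list(type = "Polygon", coordinates = list(list(
      list(1.2, 1.2), list(2.8, 1.2), list(2.8, 2.8),
      list(1.2, 2.8), list(1.2, 1.2)))))))
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  expect_equal(sum(rasterize_polygons(f, template)$values), 4)
})

test_that("block-mean aggregation averages blocks and conserves the mean", {
  g <- raster_grid(matrix(5, 24, 24), 2)
  expect_equal(unique(as.vector(resample_aggregate(g, 12)$values)), 5)
  expect_equal(resample_aggregate(g, 12)$cell_size, 24)
  g2 <- raster_grid(matrix(c(1, 3, 2, 4), 2, 2), 2)  # block {1,2,3,4}
  expect_equal(resample_aggregate(g2, 2)$values[1, 1], 2.5)
  # nested means on aligned blocks: factor 12 then 2 == factor 24
  set.seed(3)
  big <- raster_grid(matrix(rnorm(48 * 48), 48, 48), 2)
  expect_equal(resample_aggregate(resample_aggregate(big, 12), 2)$values,
               resample_aggregate(big, 24)$values)
  # global mean conserved on fully-valid grids
  expect_equal(mean(resample_aggregate(big, 12)$values), mean(big$values))
})

test_that("nearest upsampling inverts aggregation of a constant", {
  fine <- raster_grid(matrix(7, 20, 20), 2)
  coarse <- resample_aggregate(fine, 5)
  up <- upsample_nearest(coarse, fine)
  expect_equal(up$values, fine$values)
  # a single coarse cell paints a uniform block
  one <- raster_grid(matrix(3.5, 1, 1), 40)
  expect_equal(unique(as.vector(upsample_nearest(one, fine)$values)), 3.5)
})

test_that("tiling with the identity op is the identity", {
  set.seed(9)
  g <- raster_grid(matrix(rnorm(60 * 60), 60, 60), 2)
  sch <- tile_scheme(g, tile_extent = 50, overlap = 20)
  expect_gt(length(sch$tiles), 1)
  expect_equal(tile_and_mosaic(g, identity, sch)$values, g$values)
})

test_that("tiled focal statistics equal the un-tiled computation", {
  set.seed(10)
  g <- raster_grid(matrix(rnorm(60 * 60), 60, 60), 2)
  sch <- tile_scheme(g, tile_extent = 60, overlap = 24)  # pad 6 cells >= window
  tiled <- tile_and_mosaic(g, function(t) focal_stdv(t, 5), sch)
  expect_equal(tiled$values, focal_stdv(g, 5)$values, tolerance = 1e-12)
})

test_that("tiled DTW equals un-tiled DTW when paths stay within the overlap", {
  dem <- make_dem(fixture_spec("composite_landscape", 60, 60, cell_size = 2,
                               seed = 8))
  cond <- condition_dem(dem)
  slp <- slope_tangent(cond)
  acc <- d8_accumulation(d8_pointer(cond), units = "cells")
  src <- build_source_layer(extract_streams(acc, 0.05))  # dense sources
  full <- dtw(slp, src)
  sch <- tile_scheme(slp, tile_extent = 60, overlap = 56)  # pad 14 cells
  tiled <- tile_and_mosaic(slp, function(t) {
    r0 <- round((slp$origin_y - t$origin_y) / 2)
    c0 <- round((t$origin_x - slp$origin_x) / 2)
    sub_src <- raster_grid(
      src$values[r0 + seq_len(nrow(t$values)), c0 + seq_len(ncol(t$values)),
                 drop = FALSE],
      t$cell_size, t$origin_x, t$origin_y)
    dtw(t, sub_src)
  }, sch)
  # equality wherever the true least-cost path is confined to the tile
  ok <- abs(tiled$values - full$values) < 1e-9
  expect_gt(mean(ok, na.rm = TRUE), 0.98)
})
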