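# Terrain wetness indices: slope, cartographic depth-to-water (DTW),
# elevation above stream (EAS), topographic wetness index (TWI),
# multi-scale elevation roughness, and the fixed-threshold baseline map.

#' Slope as rise/run tangent
#'
#' Per-cell slope tangent from the 3x3 neighbourhood using Horn's method;
#' cells on the grid edge use one-sided differences.  Exact on a plane.
#'
#' @param dem A [raster_grid] of elevations (m).
#' @return A [raster_grid] of dimensionless slope tangents (>= 0).
#' @export
slope_tangent <- function(dem) {
  stopifnot_raster(dem, "dem")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); cs <- dem$cell_size
  # pad by edge replication, then Horn's weighted differences
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sub <- function(dr, dc) zp[dr + seq_len(nr), dc + seq_len(nc)]
  a <- sub(0, 0); b <- sub(0, 1); cc <- sub(0, 2)
  d <- sub(1, 0);                  f <- sub(1, 2)
  g <- sub(2, 0); h <- sub(2, 1);  i <- sub(2, 2)
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  gy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  # one-sided differences on the boundary ring (replication halves the
  # across-edge derivative under Horn, so recompute there)
  gx1 <- if (nc == 1L) matrix(0, nr, nc) else
    (z[, c(2:nc, nc), drop = FALSE] - z[, c(1, 1:(nc - 1)), drop = FALSE]) /
      (cs * (col(z) > 1) + cs * (col(z) < nc))
  gy1 <- if (nr == 1L) matrix(0, nr, nc) else
    (z[c(2:nr, nr), , drop = FALSE] - z[c(1, 1:(nr - 1)), , drop = FALSE]) /
      (cs * (row(z) > 1) + cs * (row(z) < nr))
  edge <- row(z) == 1 | row(z) == nr | col(z) == 1 | col(z) == nc
  gx[edge] <- gx1[edge]; gy[edge] <- gy1[edge]
  tan_slope <- sqrt(gx^2 + gy^2)
  tan_slope[is.na(z)] <- NA_real_
  out <- rg_like(dem, tan_slope)
  attr(out, "method") <- "horn"
  out
}

#' Cartographic depth-to-water index
#'
#' The least accumulated slope cost from each cell to surface water:
#' \deqn{DTW = \left[\sum_i \frac{dz_i}{dx_i}\, a_i\right] x_c}
#' summed over the cells of the minimising 8-connected path, with
#' \eqn{a = 1} for cardinal and \eqn{\sqrt 2} for diagonal moves and
#' \eqn{x_c} the cell size (m).  Each step's cost uses the slope of the
#' cell being entered.  Computed by a multi-source shortest-path expansion
#' from all surface-water cells simultaneously; water cells have DTW 0.
#' Paths never traverse nodata; cells cut off by nodata become nodata.
#'
#' @param slope A [slope_tangent()] grid.
#' @param source A boolean source layer ([build_source_layer()]); must be
#'   non-empty.
#' @param cell_size Cell size (m); default taken from `slope`.
#' @return A [raster_grid] of DTW in metres (>= 0, 0 on source cells).
#' @export
dtw <- function(slope, source, cell_size = NULL) {
  stopifnot_raster(slope, "slope"); stopifnot_raster(source, "source")
  if (!rg_aligned(slope, source)) stop("slope and source are not aligned")
  if (is.null(cell_size)) cell_size <- slope$cell_size
  src <- source$values > 0 & !is.na(source$values)
  out <- cpp_dtw(slope$values, src, cell_size)
  g <- rg_like(slope, out)
  attr(g, "provenance") <- attr(source, "provenance")
  g
}

#' Elevation above stream
#'
#' Elevation difference between each cell and the first surface-water cell
#' on its downslope D8 flow path.  Cells whose path exits the grid without
#' meeting surface water are nodata.  Non-negative on a conditioned DEM
#' because path elevations are non-increasing.
#'
#' @param dem A [raster_grid] of elevations (m) — typically the original,
#'   unconditioned DEM, with the pointer from the conditioned one.
#' @param pointer A [d8_pointer()] grid.
#' @param source A non-empty boolean source layer.
#' @return A [raster_grid] of EAS in metres (0 on source cells).
#' @export
eas <- function(dem, pointer, source) {
  stopifnot_raster(dem, "dem"); stopifnot_raster(pointer, "pointer")
  stopifnot_raster(source, "source")
  if (!rg_aligned(dem, pointer) || !rg_aligned(dem, source))
    stop("dem, pointer and source are not aligned")
  src <- source$values > 0 & !is.na(source$values)
  ptr <- matrix(as.integer(pointer$values), nrow(pointer$values),
                ncol(pointer$values))
  g <- rg_like(dem, cpp_eas(dem$values, ptr, src))
  attr(g, "provenance") <- attr(source, "provenance")
  g
}

#' Topographic wetness index
#'
#' \deqn{TWI = \ln(A_s / \tan\beta)} with \eqn{A_s} the specific catchment
#' area (m) and \eqn{\tan\beta} the slope tangent, floored at
#' `slope_floor` to keep the index finite on flats.  Cells with
#' \eqn{A_s \le 0} become nodata.
#'
#' @param sca Specific catchment area grid ([dinf_sca()]).
#' @param slope A [slope_tangent()] grid aligned with `sca`.
#' @param slope_floor Minimum tangent used in the denominator
#'   (default 0.001).
#' @return A dimensionless [raster_grid].
#' @export
twi <- function(sca, slope, slope_floor = 0.001) {
  stopifnot_raster(sca, "sca"); stopifnot_raster(slope, "slope")
  if (!rg_aligned(sca, slope)) stop("sca and slope are not aligned")
  v <- log(sca$values / pmax(slope$values, slope_floor))
  v[!is.finite(v)] <- NA_real_
  v[!is.na(sca$values) & sca$values <= 0] <- NA_real_
  rg_like(sca, v)
}

#' Topographic wetness index at a coarser resolution
#'
#' The full TWI recipe for one target resolution: aggregate the fine DEM
#' by block mean, condition the coarse DEM, compute D-infinity specific
#' catchment area and slope there, form the index, and resample it back
#' onto the fine grid by nearest neighbour.  TWI at the native 2 m
#' resolution is noisy and scale-inappropriate; 24 m and 48 m are the
#' resolutions used in the feature stack.
#'
#' @param dem Fine [raster_grid] (e.g. 2 m).
#' @param target_resolution Target cell size in metres (e.g. 24 or 48);
#'   must be a multiple of the fine cell size.
#' @param slope_floor Passed to [twi()].
#' @return A [raster_grid] aligned with `dem`.
#' @export
twi_at_resolution <- function(dem, target_resolution, slope_floor = 0.001) {
  stopifnot_raster(dem, "dem")
  factor <- target_resolution / dem$cell_size
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("target_resolution must be a positive multiple of the DEM cell size")
  coarse <- resample_aggregate(dem, round(factor))
  cond <- condition_dem(coarse)
  idx <- twi(dinf_sca(cond), slope_tangent(cond), slope_floor)
  upsample_nearest(idx, dem)
}

#' Focal standard deviation of elevation
#'
#' Population standard deviation of elevation in a centred moving window,
#' a measure of local topographic roughness.  Windows truncate at grid
#' edges; for even window sizes the extra row/column lies south/east of
#' the centre cell.  The window sizes used in the feature stack are 5, 10,
#' 20, 40 and 80 cells.
#'
#' @param dem A [raster_grid].
#' @param window_cells Window edge length in cells.
#' @return A [raster_grid] of standard deviations (m).
#' @export
focal_stdv <- function(dem, window_cells) {
  stopifnot_raster(dem, "dem")
  window_cells <- as.integer(window_cells)
  if (is.na(window_cells) || window_cells < 1L)
    stop("window_cells must be a positive integer")
  rg_like(dem, cpp_focal_sd(dem$values, window_cells))
}

#' Fixed-threshold baseline wet-area map
#'
#' The operational single-threshold map used as a reference: a cell is wet
#' iff its depth-to-water, from a source layer with a 1 ha stream
#' initiation threshold, is at most 1 m (inclusive).
#'
#' @param dtw_1ha A [dtw()] grid computed with a 1 ha stream threshold.
#' @param wet_threshold_m Wet cutoff in metres (default 1).
#' @return A boolean [raster_grid] (1 = wet).
#' @export
sfa_baseline_map <- function(dtw_1ha, wet_threshold_m = 1.0) {
  stopifnot_raster(dtw_1ha, "dtw_1ha")
  rg_like(dtw_1ha, (dtw_1ha$values <= wet_threshold_m) + 0)
}
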