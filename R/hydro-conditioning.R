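# Hydrological conditioning of the DEM.

#' Condition a DEM so that every cell drains
#'
#' Makes the elevation model hydrologically connected: after conditioning,
#' every valid cell either lies on the grid border (including cells
#' adjacent to nodata) or has a strictly lower 8-neighbour, so single-flow
#' routing is defined everywhere.  Two stages:
#'
#' 1. **Least-cost breaching.**  For each closed single-cell pit, the
#'    minimum-total-lowering path to lower ground (or to the border) is
#'    found by a cost search capped at `max_breach_length` steps, and the
#'    barrier cells along it are carved down to a monotone ramp.  A pit
#'    behind a thin barrier is drained without filling any volume.
#' 2. **Priority-flood filling with an epsilon gradient.**  Residual
#'    depressions (e.g. pits whose breach would exceed the cap) and flats
#'    are raised by the minimal amount plus `epsilon` per step so that a
#'    monotone path to the border exists from every cell.
#'
#' Elevations are only lowered by breaching and only raised by filling;
#' the epsilon increments are far below the vertical error of LiDAR
#' elevation models (~0.3 m), so derived indices are unaffected.
#'
#' @param dem A [raster_grid] of elevations (m).
#' @param max_breach_length Maximum breach-path length in cells (default 200).
#' @param epsilon Elevation increment (m) used to resolve flats
#'   (default 0.001).
#' @return A conditioned [raster_grid]; nodata is preserved.
#' @export
condition_dem <- function(dem, max_breach_length = 200, epsilon = 0.001) {
  stopifnot_raster(dem, "dem")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (max_breach_length < 0) stop("max_breach_length must be non-negative")
  out <- cpp_breach_fill(dem$values, as.integer(max_breach_length), epsilon)
  rg_like(dem, out)
}
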