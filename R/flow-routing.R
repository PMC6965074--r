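# Drainage directions, contributing areas and surface-water source layers.

#' Neighbour codes used by the D8 pointer grid
#'
#' Code 1..8 = E, NE, N, NW, W, SW, S, SE; 0 marks an outlet (border cell
#' with no lower neighbour); NA marks nodata.  This order is also the
#' deterministic tie-break order for equal steepest drops.
#' @format A named integer vector of length 8.
#' @export
D8_CODES <- c(E = 1L, NE = 2L, N = 3L, NW = 4L, W = 5L, SW = 6L, S = 7L, SE = 8L)

#' D8 flow pointer
#'
#' Assigns each cell to the 8-neighbour with the steepest downhill
#' gradient (drop divided by distance: 1 for cardinal, sqrt(2) for
#' diagonal neighbours).  The DEM must be conditioned: an interior cell
#' with no lower neighbour raises an error.  Border cells without a lower
#' neighbour become outlets (code 0).
#'
#' @param dem_conditioned A conditioned [raster_grid] (see
#'   [condition_dem()]).
#' @return A [raster_grid] of pointer codes (see [D8_CODES]).
#' @export
d8_pointer <- function(dem_conditioned) {
  stopifnot_raster(dem_conditioned, "dem_conditioned")
  ptr <- cpp_d8_pointer(dem_conditioned$values)
  g <- rg_like(dem_conditioned, ptr)
  class(g) <- c("d8_pointer", class(g))
  g
}

#' D8 flow accumulation
#'
#' Contributing area per cell: each cell contributes its own area and
#' passes the total downstream along the D8 pointer, so a cell's
#' accumulation is its own area plus that of all cells draining into it.
#' Computed in topological order; a cycle (a violated pointer invariant)
#' is an error.
#'
#' @param pointer A pointer grid from [d8_pointer()].
#' @param cell_size Cell size in metres; if `NULL`, taken from `pointer`.
#' @param units `"cells"`, `"m2"` or `"ha"`.
#' @return A [raster_grid] of accumulated area.
#' @export
d8_accumulation <- function(pointer, cell_size = NULL, units = c("cells", "m2", "ha")) {
  stopifnot_raster(pointer, "pointer")
  units <- match.arg(units)
  if (is.null(cell_size)) cell_size <- pointer$cell_size
  acc <- cpp_d8_accumulation(matrix(as.integer(pointer$values),
                                    nrow(pointer$values), ncol(pointer$values)))
  scale <- switch(units, cells = 1, m2 = cell_size^2, ha = cell_size^2 / 1e4)
  g <- rg_like(pointer, acc * scale)
  attr(g, "units") <- units
  g
}

#' D-infinity specific catchment area
#'
#' Flow directions by Tarboton's triangular-facet method: the steepest of
#' the eight facets around a cell defines a continuous flow angle, and the
#' cell's accumulated area is split between the facet's two neighbours in
#' proportion to the angle.  Only facets fully inside the valid grid are
#' considered; cells without a downslope in-grid facet (typically border
#' cells facing off-grid) are sinks whose accumulation leaves the domain,
#' so total edge outflow equals total valid area — a conservation audit
#' returned as an attribute.  The specific catchment
#' area is accumulated area per unit contour width (divided by cell size).
#'
#' @param dem_conditioned A conditioned [raster_grid].
#' @return A [raster_grid] of specific catchment area (m), with attribute
#'   `edge_outflow_m2` for the conservation audit.
#' @export
dinf_sca <- function(dem_conditioned) {
  stopifnot_raster(dem_conditioned, "dem_conditioned")
  res <- cpp_dinf_accumulation(dem_conditioned$values, dem_conditioned$cell_size)
  g <- rg_like(dem_conditioned, res$acc_m2 / dem_conditioned$cell_size)
  attr(g, "edge_outflow_m2") <- res$edge_outflow_m2
  g
}

#' Extract a stream network from flow accumulation
#'
#' A cell is a stream cell iff its contributing area reaches the
#' initiation threshold (inclusive, so stream sets are exactly nested
#' across thresholds).  On a 2 m grid, 1 ha corresponds to 2500 cells.
#'
#' @param acc Accumulation grid from [d8_accumulation()] (any units; the
#'   `units` attribute set there is honoured).
#' @param threshold_ha Stream initiation threshold in hectares.
#' @return A boolean [raster_grid] (1 = stream).
#' @export
extract_streams <- function(acc, threshold_ha) {
  stopifnot_raster(acc, "acc")
  if (threshold_ha <= 0) stop("threshold_ha must be positive")
  units <- attr(acc, "units")
  if (is.null(units)) units <- "cells"
  thr <- switch(units,
    cells = threshold_ha * 1e4 / acc$cell_size^2,
    m2 = threshold_ha * 1e4,
    ha = threshold_ha)
  g <- rg_like(acc, (acc$values >= thr) + 0)
  attr(g, "threshold_ha") <- threshold_ha
  g
}

#' Merge extracted streams with mapped surface water
#'
#' Cellwise OR of the extracted stream raster and a rasterized water mask
#' (lakes and rivers), giving the source layer of surface-water cells from
#' which depth-to-water and elevation-above-stream are measured.
#'
#' @param streams Boolean [raster_grid] of stream cells.
#' @param water_mask Optional boolean [raster_grid] of mapped water; `NULL`
#'   for none.
#' @return A boolean [raster_grid] with attribute `provenance` recording
#'   the stream threshold and whether a water mask was merged.
#' @export
build_source_layer <- function(streams, water_mask = NULL) {
  stopifnot_raster(streams, "streams")
  v <- streams$values > 0 & !is.na(streams$values)
  if (!is.null(water_mask)) {
    stopifnot_raster(water_mask, "water_mask")
    if (!rg_aligned(streams, water_mask))
      stop("streams and water_mask are not aligned")
    v <- v | (water_mask$values > 0 & !is.na(water_mask$values))
  }
  out <- v + 0
  out[is.na(streams$values)] <- NA_real_
  g <- rg_like(streams, out)
  attr(g, "provenance") <- list(threshold_ha = attr(streams, "threshold_ha"),
                                water_mask = !is.null(water_mask))
  g
}
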