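# Raster data model and plumbing shared by every terrain module.
#
# Grids are north-up: values[1, 1] is the north-west cell.  The origin is
# the outer corner of that cell, so a point (x, y) falls in
#   col = floor((x - origin_x) / cell_size) + 1
#   row = floor((origin_y - y) / cell_size) + 1
# and cell centres sit at half-cell offsets.  Nodata is carried as NA
# internally; the sentinel only exists on disk.

#' Construct a raster grid
#'
#' A `raster_grid` is the common currency of all terrain operations: a
#' north-up matrix of cell values with square cells, a map origin at the
#' outer corner of the top-left cell, and an opaque CRS tag.  The CRS must
#' be projected with metre units; terrain indices (least-cost depth-to-water,
#' area thresholds in hectares) are metric and geographic coordinates are
#' rejected at I/O time.
#'
#' @param values Numeric matrix, row 1 = northernmost row. `NA` marks nodata.
#' @param cell_size Cell edge length in metres (> 0, square cells).
#' @param origin_x,origin_y Map coordinates (m) of the outer corner of the
#'   top-left cell (west edge, north edge).
#' @param crs_tag Free-text CRS label carried through unchanged.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin_x = 0, origin_y = NULL,
                        crs_tag = "local-metric") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(values) == 0L) stop("raster must have at least one cell")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number (metres)")
  if (is.null(origin_y)) origin_y <- nrow(values) * cell_size
  g <- structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_tag = as.character(crs_tag)),
    class = "raster_grid")
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d rows x %d cols @ %g m (crs: %s)\n",
              nrow(v), ncol(v), x$cell_size, x$crs_tag))
  cat(sprintf("  origin (top-left corner): %.3f, %.3f\n", x$origin_x, x$origin_y))
  cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

stopifnot_raster <- function(x, what = "grid") {
  if (!is_raster_grid(x)) stop(what, " must be a raster_grid")
  invisible(x)
}

# Rebuild a grid with new values but the same georeference.
rg_like <- function(template, values) {
  raster_grid(values, template$cell_size, template$origin_x,
              template$origin_y, template$crs_tag)
}

# Two grids share the same geometry (shape, cell size, origin)?
rg_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

# Map coordinates of all cell centres (vectors along each axis).
rg_centres_x <- function(g) g$origin_x + (seq_len(ncol(g$values)) - 0.5) * g$cell_size
rg_centres_y <- function(g) g$origin_y - (seq_len(nrow(g$values)) - 0.5) * g$cell_size

# Point -> (row, col), floor convention; NA outside the grid.
rg_cell_of <- function(g, x, y) {
  col <- floor((x - g$origin_x) / g$cell_size) + 1
  row <- floor((g$origin_y - y) / g$cell_size) + 1
  bad <- col < 1 | col > ncol(g$values) | row < 1 | row > nrow(g$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read a single-band raster
#'
#' Reads an ESRI ASCII grid (`.asc`), the plain-text interchange raster
#' format (header keywords `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`).  Cells equal to the nodata sentinel are
#' masked to `NA`.  GeoTIFF input is not handled by this build and is
#' rejected with an explicit error; convert to ASCII grid first
#' (`gdal_translate -of AAIGrid` in any GDAL installation).
#'
#' @param path File to read.
#' @param format `"ascii_grid"` (default) or `"geotiff"`.
#' @param crs_tag CRS label to attach (ASCII grids carry no CRS).
#' @return A [raster_grid].
#' @export
read_raster <- function(path, format = c("ascii_grid", "geotiff"),
                        crs_tag = "local-metric") {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF I/O is not supported by this build; ",
         "convert to ESRI ASCII grid (format = \"ascii_grid\")")
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value", "dx", "dy")) {
      hdr[[key]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  if (is.null(hdr$cellsize) && !is.null(hdr$dx) && !is.null(hdr$dy)) {
    if (abs(hdr$dx - hdr$dy) > 1e-12)
      stop("non-square cells (dx != dy) are not supported: ", path)
    hdr$cellsize <- hdr$dx
  }
  for (need in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[need]]))
      stop("ASCII grid header is missing '", need, "': ", path)
  if (is.null(hdr$xllcorner)) {
    if (is.null(hdr$xllcenter))
      stop("ASCII grid header has no x georeference (xllcorner/xllcenter): ", path)
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  }
  if (hdr$cellsize <= 0) stop("cellsize must be positive: ", path)
  # heuristic: lat/lon degrees are not metres
  if (hdr$cellsize < 0.01 && abs(hdr$xllcorner) <= 360 && abs(hdr$yllcorner) <= 90)
    stop("grid appears to be in geographic coordinates (degrees); ",
         "a projected CRS in metres is required")
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE,
               na.strings = character())
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d cell values, found %d: %s", nr * nc,
                 length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, hdr$cellsize,
              origin_x = hdr$xllcorner,
              origin_y = hdr$yllcorner + nr * hdr$cellsize,
              crs_tag = crs_tag)
}

#' Write a single-band raster
#'
#' Writes an ESRI ASCII grid readable by common GIS software.  `NA` cells
#' are written as the `nodata` sentinel.  Values are printed with 17
#' significant digits, so a read/write round trip is value-identical for
#' doubles (and hence for float32-representable data).
#'
#' @param grid A [raster_grid].
#' @param path Output file.
#' @param format `"ascii_grid"` (the only supported on-disk format).
#' @param nodata Sentinel written for `NA` cells.
#' @export
write_raster <- function(grid, path, format = c("ascii_grid", "geotiff"),
                         nodata = -9999) {
  stopifnot_raster(grid)
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF I/O is not supported by this build; ",
         "use format = \"ascii_grid\"")
  v <- grid$values
  if (any(!is.na(v) & v == nodata))
    stop("nodata sentinel ", nodata, " occurs as a legitimate cell value; ",
         "choose a different sentinel")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", grid$origin_x),
    sprintf("yllcorner %.10f", grid$origin_y - nrow(v) * grid$cell_size),
    sprintf("cellsize %.10f", grid$cell_size),
    sprintf("NODATA_value %s", format(nodata, scientific = FALSE))), con)
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " "))
  writeLines(rows, con)
  invisible(NULL)
}

#' Rasterize polygons onto a template grid
#'
#' Burns a set of polygons (e.g. lake and river outlines from a property
#' map) into a boolean grid: a cell is `TRUE` iff its centre lies inside
#' any polygon (even-odd rule, so polygons with holes work).  Polygons may
#' be a GeoJSON file path, a parsed GeoJSON list, or a list of n x 2
#' coordinate matrices (rings).
#'
#' @param polygons Polygon set (see Details) in the template CRS.
#' @param template A [raster_grid] supplying the geometry.
#' @return A boolean [raster_grid] (values 1/0).  An empty polygon set
#'   gives an all-`FALSE` grid.
#' @export
rasterize_polygons <- function(polygons, template) {
  stopifnot_raster(template, "template")
  rings <- as_polygon_rings(polygons)
  nr <- nrow(template$values); nc <- ncol(template$values)
  xs <- rep(rg_centres_x(template), each = nr)
  ys <- rep(rg_centres_y(template), times = nc)
  crossings <- integer(nr * nc)
  for (ring in rings) {
    rx <- ring[, 1]; ry <- ring[, 2]
    n <- length(rx)
    if (n < 3L) next
    if (rx[1] == rx[n] && ry[1] == ry[n]) { rx <- rx[-n]; ry <- ry[-n]; n <- n - 1L }
    # quick reject: template entirely outside the ring's bounding box
    if (max(rx) < template$origin_x ||
        min(rx) > template$origin_x + nc * template$cell_size ||
        max(ry) < template$origin_y - nr * template$cell_size ||
        min(ry) > template$origin_y) next
    j <- n
    for (i in seq_len(n)) {
      hit <- (ry[i] > ys) != (ry[j] > ys)
      if (any(hit)) {
        xint <- rx[i] + (ys[hit] - ry[i]) / (ry[j] - ry[i]) * (rx[j] - rx[i])
        idx <- which(hit)[xs[hit] < xint]
        crossings[idx] <- crossings[idx] + 1L
      }
      j <- i
    }
  }
  rg_like(template, matrix(as.double(crossings %% 2L == 1L), nr, nc))
}

# Normalize polygon input to a flat list of n x 2 ring matrices.
as_polygon_rings <- function(polygons) {
  if (is.character(polygons) && length(polygons) == 1L)
    polygons <- jsonlite::read_json(polygons, simplifyVector = FALSE)
  if (is.matrix(polygons)) polygons <- list(polygons)
  if (is.list(polygons) && !is.null(polygons$type)) {
    gj <- polygons
    feats <- switch(gj$type,
      FeatureCollection = lapply(gj$features, `[[`, "geometry"),
      Feature = list(gj$geometry),
      Polygon = , MultiPolygon = list(gj),
      stop("unsupported GeoJSON type: ", gj$type))
    rings <- list()
    for (geom in feats) {
      if (is.null(geom)) next
      polys <- if (geom$type == "Polygon") list(geom$coordinates)
               else if (geom$type == "MultiPolygon") geom$coordinates
               else stop("unsupported geometry type: ", geom$type)
      for (poly in polys)
        for (ring in poly)
          rings[[length(rings) + 1L]] <-
            do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    }
    return(rings)
  }
  if (is.list(polygons)) {
    if (length(polygons) == 0L) return(list())
    if (all(vapply(polygons, is.matrix, TRUE))) return(polygons)
  }
  stop("polygons must be a GeoJSON path/list or a list of coordinate matrices")
}

#' Aggregate a raster to a coarser resolution by block mean
#'
#' Each output cell is the mean of the `factor` x `factor` block of valid
#' input cells beneath it (the resampling used to take a 2 m elevation
#' model to 24 m and 48 m for wetness-index calculation).  Blocks that are
#' entirely nodata become nodata; partial blocks at the south/east margins
#' average whatever cells exist.
#'
#' @param grid A [raster_grid].
#' @param factor Positive integer block size.
#' @return A [raster_grid] with `cell_size * factor`.
#' @export
resample_aggregate <- function(grid, factor) {
  stopifnot_raster(grid)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  nro <- ceiling(nr / factor); nco <- ceiling(nc / factor)
  ri <- rep(seq_len(nro), each = factor, length.out = nr)[seq_len(nr)]
  ci <- rep(seq_len(nco), each = factor, length.out = nc)[seq_len(nc)]
  grp <- outer(ri, (ci - 1L) * nro, `+`)
  sums <- tapply(as.vector(v), as.vector(grp), function(b)
    if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE))
  out <- matrix(NA_real_, nro, nco)
  out[as.integer(names(sums))] <- as.numeric(sums)
  raster_grid(out, grid$cell_size * factor, grid$origin_x, grid$origin_y,
              grid$crs_tag)
}

#' Resample a coarse raster onto a fine template by nearest neighbour
#'
#' Each template cell takes the value of the coarse cell containing its
#' centre (used to place 24 m / 48 m wetness indices back into the fine
#' feature stack).  Template centres outside the coarse grid become nodata.
#'
#' @param grid Coarse [raster_grid].
#' @param template Fine [raster_grid] supplying the output geometry.
#' @return A [raster_grid] aligned with `template`.
#' @export
upsample_nearest <- function(grid, template) {
  stopifnot_raster(grid); stopifnot_raster(template, "template")
  cell <- rg_cell_of(grid,
                     rep(rg_centres_x(template), each = nrow(template$values)),
                     rep(rg_centres_y(template), times = ncol(template$values)))
  out <- rep(NA_real_, length(cell$row))
  ok <- !is.na(cell$row)
  out[ok] <- grid$values[cbind(cell$row[ok], cell$col[ok])]
  rg_like(template, matrix(out, nrow(template$values), ncol(template$values)))
}

#' Build a regular tiling scheme with overlap
#'
#' Terrain operations with finite spatial reach (focal statistics,
#' least-cost depth-to-water) are run per tile and mosaicked; the overlap
#' absorbs edge artefacts.  Defaults mirror a production setting of 2 km
#' overlap between processing units.
#'
#' @param grid A [raster_grid] to tile.
#' @param tile_extent Tile edge length in metres.
#' @param overlap Overlap between adjacent tiles in metres.
#' @return A `tile_scheme`: list of tile windows (row/col ranges of the
#'   padded tile and of its core).
#' @export
tile_scheme <- function(grid, tile_extent, overlap = 2000) {
  stopifnot_raster(grid)
  if (overlap < 0) stop("overlap must be non-negative")
  if (overlap >= tile_extent) stop("overlap must be smaller than tile_extent")
  cs <- grid$cell_size
  core <- max(1L, as.integer(round(tile_extent / cs)))
  pad <- as.integer(ceiling(overlap / cs / 2))  # half the overlap each side
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  tiles <- list()
  for (r0 in seq(1L, nr, by = core)) {
    for (c0 in seq(1L, nc, by = core)) {
      r1 <- min(nr, r0 + core - 1L); c1 <- min(nc, c0 + core - 1L)
      tiles[[length(tiles) + 1L]] <- list(
        core_rows = c(r0, r1), core_cols = c(c0, c1),
        rows = c(max(1L, r0 - pad), min(nr, r1 + pad)),
        cols = c(max(1L, c0 - pad), min(nc, c1 + pad)))
    }
  }
  structure(list(tiles = tiles, tile_extent = tile_extent, overlap = overlap,
                 cell_size = cs), class = "tile_scheme")
}

#' Apply a raster operation tile-by-tile and mosaic the result
#'
#' Runs `op` (a function `raster_grid -> raster_grid` of identical shape)
#' on each padded tile and keeps, for every cell, the value from the tile
#' in which the cell lies deepest inside the padded window ("farthest from
#' a tile boundary wins").  If the operation's edge artefacts are confined
#' within the overlap, the mosaic equals running `op` on the whole grid.
#'
#' @param grid A [raster_grid].
#' @param op Function taking and returning a [raster_grid] of equal shape.
#' @param scheme A [tile_scheme] for `grid`.
#' @return A [raster_grid].
#' @export
tile_and_mosaic <- function(grid, op, scheme) {
  stopifnot_raster(grid)
  if (!inherits(scheme, "tile_scheme")) stop("scheme must be a tile_scheme")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  out <- matrix(NA_real_, nr, nc)
  depth <- matrix(-1, nr, nc)
  for (tl in scheme$tiles) {
    rows <- tl$rows[1]:tl$rows[2]; cols <- tl$cols[1]:tl$cols[2]
    sub <- raster_grid(grid$values[rows, cols, drop = FALSE], grid$cell_size,
                       grid$origin_x + (tl$cols[1] - 1L) * grid$cell_size,
                       grid$origin_y - (tl$rows[1] - 1L) * grid$cell_size,
                       grid$crs_tag)
    res <- op(sub)
    stopifnot_raster(res, "tile operation result")
    if (!identical(dim(res$values), dim(sub$values)))
      stop("tile operation changed the tile shape")
    # distance (cells) from each tile cell to the nearest padded-tile edge;
    # edges coinciding with the grid boundary carry no artefacts and are
    # ignored (distance infinite)
    d_top <- if (tl$rows[1] == 1L) rep(Inf, length(rows)) else seq_along(rows) - 1
    d_bot <- if (tl$rows[2] == nr) rep(Inf, length(rows)) else rev(seq_along(rows)) - 1
    d_lef <- if (tl$cols[1] == 1L) rep(Inf, length(cols)) else seq_along(cols) - 1
    d_rig <- if (tl$cols[2] == nc) rep(Inf, length(cols)) else rev(seq_along(cols)) - 1
    d <- outer(pmin(d_top, d_bot), pmin(d_lef, d_rig), pmin)
    better <- d > depth[rows, cols]
    blk_out <- out[rows, cols]; blk_dep <- depth[rows, cols]
    blk_out[better] <- res$values[rows - tl$rows[1] + 1L,
                                  cols - tl$cols[1] + 1L][better]
    blk_dep[better] <- d[better]
    out[rows, cols] <- blk_out; depth[rows, cols] <- blk_dep
  }
  rg_like(grid, out)
}
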