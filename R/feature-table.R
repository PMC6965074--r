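# Plot-level training matrix: raster sampling at plot locations, label
# recoding, and collinearity filtering.

#' Recode the five soil-moisture classes to a binary wet/dry label
#'
#' Dry and mesic plots (groundwater deeper than ~1 m) become `"dry"`;
#' mesic-moist, moist and wet plots (groundwater within ~1 m of the
#' surface at least seasonally) become `"wet"`.  With the national class
#' marginals of 6/54/27/10/3 % this yields a 60/40 dry/wet split.
#'
#' @param moisture_class Character or factor vector with values in
#'   `dry`, `mesic`, `mesic_moist`, `moist`, `wet`.
#' @return Factor with levels `dry`, `wet`.
#' @export
recode_binary <- function(moisture_class) {
  x <- as.character(moisture_class)
  bad <- !(x %in% MOISTURE_CLASSES) & !is.na(x)
  if (any(bad))
    stop("unknown moisture class: ", paste(unique(x[bad]), collapse = ", "))
  factor(ifelse(x %in% c("dry", "mesic"), "dry", "wet"),
         levels = c("dry", "wet"))
}

#' Sample a stack of rasters at plot locations
#'
#' Each plot takes the value of the cell containing its coordinate (floor
#' convention; a point on a cell boundary belongs to the cell south/east
#' of it).  Plots that fall outside the grids or on nodata in any layer
#' are dropped; the count and ids of dropped plots are attached as the
#' `dropped` attribute and reported via `message()`.
#'
#' @param plots Data frame with at least `plot_id`, `x`, `y`; label
#'   columns (`moisture_class`, `binary_label`) are carried through.
#' @param layers Named list of aligned [raster_grid]s.
#' @return Data frame: plot columns plus one numeric column per layer.
#' @export
sample_rasters <- function(plots, layers) {
  if (!all(c("plot_id", "x", "y") %in% names(plots)))
    stop("plots must have columns plot_id, x, y")
  if (length(layers) == 0L || is.null(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("layers must be a non-empty named list of raster_grid objects")
  if (anyDuplicated(names(layers))) stop("layer names must be unique")
  ref <- layers[[1L]]
  for (g in layers) {
    stopifnot_raster(g, "every layer")
    if (!rg_aligned(ref, g)) stop("all layers must share the same geometry")
  }
  cell <- rg_cell_of(ref, plots$x, plots$y)
  vals <- lapply(layers, function(g) {
    out <- rep(NA_real_, nrow(plots))
    ok <- !is.na(cell$row)
    out[ok] <- g$values[cbind(cell$row[ok], cell$col[ok])]
    out
  })
  tab <- cbind(plots, as.data.frame(vals, optional = TRUE))
  keep <- stats::complete.cases(tab[names(layers)])
  if (any(!keep))
    message(sum(!keep), " plot(s) dropped (outside extent or on nodata)")
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- plots$plot_id[!keep]
  out
}

#' Iterative collinearity filter
#'
#' While any pair of feature columns has absolute Pearson correlation
#' above `r_threshold`, the member of the worst (most correlated) pair
#' with the larger mean absolute correlation against all remaining
#' features is dropped.  Mirrors the common pre-modelling practice of
#' removing near-duplicate terrain layers before classification.
#'
#' @param table Data frame; only numeric columns not named in `exclude`
#'   are considered features.
#' @param r_threshold Correlation cutoff (default 0.9, exclusive: pairs
#'   strictly above it are collinear).
#' @param exclude Column names treated as metadata, never dropped and
#'   never counted as features (ids, raw plot coordinates, labels; the
#'   sampled `X_Coord`/`Y_Coord` layers are the coordinate features).
#' @return The filtered data frame with attribute `dropped_columns`, a
#'   data frame listing each dropped column, its partner and their
#'   correlation, in drop order.
#' @export
collinearity_filter <- function(table, r_threshold = 0.9,
                                exclude = c("plot_id", "x", "y",
                                            "moisture_class",
                                            "binary_label")) {
  feats <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], exclude)
  dropped <- data.frame(column = character(), partner = character(),
                        correlation = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (length(feats) < 2L) break
    cm <- suppressWarnings(abs(cor(table[feats],
                                   use = "pairwise.complete.obs")))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    if (max(cm) <= r_threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- feats[worst]
    mean_abs <- rowMeans(cm[pair, , drop = FALSE])
    drop <- pair[which.max(mean_abs)]
    keep_partner <- setdiff(pair, drop)
    dropped[nrow(dropped) + 1L, ] <- list(drop, keep_partner, max(cm))
    feats <- setdiff(feats, drop)
  }
  out <- table[, !(names(table) %in% dropped$column), drop = FALSE]
  attr(out, "dropped_columns") <- dropped
  out
}
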