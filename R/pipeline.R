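# End-to-end orchestration: condition -> flow -> indices -> features ->
# train -> evaluate -> map, driven by a config list or YAML file.

#' Build a pipeline configuration
#'
#' Defaults reproduce the standard index stack: stream initiation
#' thresholds 0.5/1/2/5/10/15/30 ha, roughness windows 5/10/20/40/80
#' cells, wetness-index resolutions 24 m and 48 m, and 2 km tiling
#' overlap.
#'
#' @param dem Path to a DEM (ASCII grid) or a [raster_grid].
#' @param plots Path to a plots CSV (`plot_id,x,y,moisture_class`) or a
#'   data frame.
#' @param water Optional water-polygon GeoJSON path, polygon list, or
#'   boolean [raster_grid].
#' @param ancillary Optional named list of aligned [raster_grid]s (or
#'   ASCII-grid paths) appended to the feature stack as-is.
#' @param stream_thresholds_ha Stream initiation thresholds (ha).
#' @param stdv_windows Roughness window sizes (cells).
#' @param twi_resolutions TWI target resolutions (m).
#' @param tile_overlap Tiling overlap (m) recorded for provenance.
#' @param learners Character vector of learners to train (see
#'   [train_spec()]).
#' @param wet_threshold_m Baseline-map wet cutoff (m).
#' @param baseline_threshold_ha Baseline-map stream threshold (ha).
#' @param collinearity_r Collinearity cutoff for [collinearity_filter()].
#' @param seed Integer seed for the split, folds and stochastic learners.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dem, plots, water = NULL, ancillary = NULL,
                            stream_thresholds_ha = c(0.5, 1, 2, 5, 10, 15, 30),
                            stdv_windows = c(5, 10, 20, 40, 80),
                            twi_resolutions = c(24, 48),
                            tile_overlap = 2000,
                            learners = "random_forest",
                            wet_threshold_m = 1.0,
                            baseline_threshold_ha = 1.0,
                            collinearity_r = 0.9,
                            seed = 1L) {
  if (length(stream_thresholds_ha) == 0L)
    stop("stream_thresholds_ha must be non-empty")
  if (any(stream_thresholds_ha <= 0)) stop("stream thresholds must be positive")
  if (length(stdv_windows) == 0L) stop("stdv_windows must be non-empty")
  if (!all(learners %in% LEARNERS))
    stop("unknown learner(s): ", paste(setdiff(learners, LEARNERS), collapse = ", "))
  structure(list(dem = dem, plots = plots, water = water,
                 ancillary = ancillary,
                 stream_thresholds_ha = sort(stream_thresholds_ha),
                 stdv_windows = stdv_windows,
                 twi_resolutions = twi_resolutions,
                 tile_overlap = tile_overlap, learners = learners,
                 wet_threshold_m = wet_threshold_m,
                 baseline_threshold_ha = baseline_threshold_ha,
                 collinearity_r = collinearity_r,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Compute the terrain-index feature stack
#'
#' The index layers derived from one DEM: for each stream threshold a DTW
#' and an EAS layer, a TWI layer per target resolution, a roughness layer
#' per window, plus `Elevation`, `X_Coord` and `Y_Coord`.  Names follow
#' the conventional scheme `DTW_<T>`, `EAS_<T>`, `TWI_<m>`, `STDV_<w>`.
#'
#' @param dem A [raster_grid].
#' @param water Optional boolean water mask aligned with `dem`.
#' @param config A [pipeline_config()] (paths inside it are ignored here).
#' @return Named list of aligned [raster_grid]s, with attributes
#'   `conditioned`, `pointer`, `accumulation` for reuse.
#' @export
compute_index_stack <- function(dem, water = NULL, config = pipeline_config(dem, NULL)) {
  stopifnot_raster(dem, "dem")
  cond <- condition_dem(dem)
  ptr <- d8_pointer(cond)
  acc <- d8_accumulation(ptr, units = "cells")
  slp <- slope_tangent(cond)
  layers <- list()
  for (thr in config$stream_thresholds_ha) {
    src <- build_source_layer(extract_streams(acc, thr), water)
    if (!any(src$values > 0, na.rm = TRUE)) {
      warning("no source cells at threshold ", thr,
              " ha; skipping DTW/EAS at this threshold")
      next
    }
    tag <- format_threshold(thr)
    layers[[paste0("DTW_", tag)]] <- dtw(slp, src)
    layers[[paste0("EAS_", tag)]] <- eas(dem, ptr, src)
  }
  for (res in config$twi_resolutions)
    layers[[paste0("TWI_", res)]] <- twi_at_resolution(dem, res)
  for (w in config$stdv_windows)
    layers[[paste0("STDV_", w)]] <- focal_stdv(dem, w)
  layers[["Elevation"]] <- dem
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  layers[["X_Coord"]] <- rg_like(dem, matrix(rep(rg_centres_x(dem), each = nr), nr, nc))
  layers[["Y_Coord"]] <- rg_like(dem, matrix(rep(rg_centres_y(dem), times = nc), nr, nc))
  attr(layers, "conditioned") <- cond
  attr(layers, "pointer") <- ptr
  attr(layers, "accumulation") <- acc
  layers
}

format_threshold <- function(thr) {
  s <- format(thr, trim = TRUE, scientific = FALSE)
  gsub("\\.", "_", s)
}

#' Run the full wet-area mapping pipeline
#'
#' Conditions the DEM, derives the full index stack, samples it at the
#' plots, recodes and filters the feature table, splits 75/25, tunes each
#' requested learner by 10-fold cross-validated grid search, evaluates on
#' the held-out quarter, evaluates the fixed-threshold baseline map on the
#' same test plots, and writes every artefact (rasters, tables, models,
#' reports, resolved config, log) into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing artefacts.
#' @return Invisibly, a list: `layers`, `features`, `models`,
#'   `reports` (one [evaluation_report()] per learner),
#'   `baseline_report`, `importance` (random forest only), `maps`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    message(msg); log_lines <<- c(log_lines, msg)
  }

  dem <- if (is_raster_grid(config$dem)) config$dem else read_raster(config$dem)
  plots <- if (is.data.frame(config$plots)) config$plots else read.csv(config$plots)
  water <- config$water
  if (!is.null(water) && !is_raster_grid(water))
    water <- rasterize_polygons(water, dem)

  say("deriving index stack (", length(config$stream_thresholds_ha),
      " stream thresholds)")
  layers <- compute_index_stack(dem, water, config)
  ancillary <- config$ancillary
  if (!is.null(ancillary)) {
    ancillary <- lapply(ancillary, function(a)
      if (is_raster_grid(a)) a else read_raster(a))
    layers <- c(layers, ancillary)
  }

  say("sampling ", length(layers), " layers at ", nrow(plots), " plots")
  if (!"binary_label" %in% names(plots))
    plots$binary_label <- recode_binary(plots$moisture_class)
  feats <- sample_rasters(plots, layers)
  feats <- collinearity_filter(feats, config$collinearity_r)
  say(nrow(attr(feats, "dropped_columns")), " collinear column(s) dropped")

  split <- split_train_test(feats, 0.75, config$seed)
  models <- list(); reports <- list()
  for (ln in config$learners) {
    say("training ", ln)
    spec <- train_spec(ln, seed = config$seed)
    models[[ln]] <- tune_and_train(split$train, spec)
    reports[[ln]] <- evaluate_classifier(models[[ln]], split$test)
    say(ln, sprintf(": test kappa %.3f", reports[[ln]]$kappa))
  }

  # fixed-threshold baseline on the same test plots
  base_tag <- paste0("DTW_", format_threshold(config$baseline_threshold_ha))
  baseline_report <- NULL
  if (base_tag %in% names(layers)) {
    wet_pred <- factor(ifelse(split$test[[base_tag]] <= config$wet_threshold_m,
                              "wet", "dry"), levels = c("dry", "wet"))
    obs <- factor(split$test$binary_label, levels = c("dry", "wet"))
    baseline_report <- evaluation_report(table(observed = obs, predicted = wet_pred))
    say(sprintf("baseline map: test kappa %.3f", baseline_report$kappa))
  }

  importance <- NULL
  if ("random_forest" %in% names(models))
    importance <- permutation_importance(models$random_forest, split$test,
                                         seed = config$seed)

  maps <- list()
  if (length(models)) {
    best <- names(models)[which.max(vapply(reports, `[[`, 0, "kappa"))]
    say("predicting map with ", best)
    maps <- predict_map(models[[best]], layers)
    maps$learner <- best
  }

  result <- list(layers = layers, features = feats, split = split,
                 models = models, reports = reports,
                 baseline_report = baseline_report,
                 importance = importance, maps = maps)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(layers))
      write_raster(layers[[nm]], file.path(out_dir, paste0(nm, ".asc")))
    if (length(maps)) {
      write_raster(maps$class, file.path(out_dir, "wet_class.asc"))
      write_raster(maps$probability, file.path(out_dir, "wet_probability.asc"))
    }
    write.csv(feats, file.path(out_dir, "feature_table.csv"), row.names = FALSE)
    if (!is.null(importance))
      write.csv(importance, file.path(out_dir, "importance.csv"),
                row.names = FALSE)
    report_json <- lapply(reports, unclass)
    report_json$baseline <- if (!is.null(baseline_report))
      unclass(baseline_report)
    jsonlite::write_json(report_json, file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    cfg_echo <- config
    cfg_echo$dem <- if (is.character(config$dem)) config$dem else "<in-memory raster>"
    cfg_echo$plots <- if (is.character(config$plots)) config$plots else "<in-memory table>"
    cfg_echo$water <- if (is.null(config$water)) NULL
      else if (is.character(config$water)) config$water else "<in-memory layer>"
    cfg_echo$ancillary <- if (is.null(config$ancillary)) NULL else names(config$ancillary)
    jsonlite::write_json(unclass(cfg_echo), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    saveRDS(models, file.path(out_dir, "models.rds"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(result)
}
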