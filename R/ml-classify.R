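# Supervised wet/dry classification: train/tune the four learner families,
# evaluate with chance-corrected agreement, and rasterize predictions.
#
# The grid search + 10-fold cross-validation loop is written out here
# (rather than delegated to a meta-framework) so that the selection metric
# is exactly the Cohen's kappa reported downstream and every learner runs
# through the identical folds.

LEARNERS <- c("random_forest", "svm_rbf", "neural_net", "naive_bayes")

default_grid <- function(learner) {
  switch(learner,
    random_forest = expand.grid(mtry = c(2, 4, 8, 16)),
    svm_rbf = expand.grid(cost = 10^(-1:2), gamma = 10^(-3:0)),
    neural_net = expand.grid(size = c(5, 10, 20), decay = c(0, 0.001, 0.01)),
    naive_bayes = expand.grid(laplace = 0),
    stop("unknown learner: ", learner))
}

#' Specify a classifier training run
#'
#' @param learner One of `"random_forest"`, `"svm_rbf"`, `"neural_net"`,
#'   `"naive_bayes"`.
#' @param grid Data frame of hyperparameter combinations; `NULL` for the
#'   built-in default grid (random forest: `mtry` in 2/4/8/16 with 500
#'   trees; RBF SVM: `cost` 0.1-100 by decades, `gamma` 0.001-1; neural
#'   net: one hidden layer of 5/10/20 units, weight decay 0/0.001/0.01;
#'   naive Bayes: Gaussian class-conditionals, no tuning).
#' @param cv_folds Cross-validation folds (default 10).
#' @param train_fraction Fraction of rows used for training in
#'   [split_train_test()] (default 0.75).
#' @param seed Integer seed for fold assignment and stochastic learners.
#' @return A `train_spec` list.
#' @export
train_spec <- function(learner = LEARNERS, grid = NULL, cv_folds = 10,
                       train_fraction = 0.75, seed = 1L) {
  learner <- match.arg(learner)
  if (is.null(grid)) grid <- default_grid(learner)
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("grid must be a non-empty data frame")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(learner = learner, grid = grid,
                 cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction,
                 selection_metric = "kappa", seed = as.integer(seed)),
            class = "train_spec")
}

#' Random 75/25 train/test split
#'
#' Simple (unstratified) random split, reproducible under the seed; the
#' two parts are disjoint and exhaustive.
#'
#' @param table Feature data frame.
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(table, fraction = 0.75, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(table)
  set.seed(seed)
  idx <- sample.int(n, floor(fraction * n))
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

# ---- learner backends ------------------------------------------------------

# standardization for scale-sensitive learners
fit_scaler <- function(X) {
  mu <- vapply(X, mean, 0); s <- vapply(X, sd, 0)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, s = s)
}
apply_scaler <- function(X, sc) {
  as.data.frame(Map(function(col, m, s) (col - m) / s, X, sc$mu, sc$s),
                optional = TRUE)
}

fit_one <- function(learner, params, X, y, seed) {
  set.seed(seed)
  scaler <- NULL
  if (learner %in% c("svm_rbf", "neural_net")) {
    scaler <- fit_scaler(X)
    X <- apply_scaler(X, scaler)
  }
  fit <- switch(learner,
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = 500, mtry = min(params$mtry, ncol(X))),
    svm_rbf = e1071::svm(
      x = as.matrix(X), y = y, kernel = "radial", cost = params$cost,
      gamma = params$gamma, probability = TRUE),
    neural_net = nnet::nnet(
      x = as.matrix(X), y = as.numeric(y == "wet"), size = params$size,
      decay = params$decay, maxit = 300, entropy = TRUE, trace = FALSE,
      MaxNWts = 5000),
    naive_bayes = e1071::naiveBayes(x = X, y = y, laplace = params$laplace))
  list(learner = learner, fit = fit, scaler = scaler)
}

predict_prob_wet <- function(backend, X) {
  if (!is.null(backend$scaler)) X <- apply_scaler(X, backend$scaler)
  switch(backend$learner,
    random_forest = unname(predict(backend$fit, X, type = "prob")[, "wet"]),
    svm_rbf = {
      pr <- predict(backend$fit, as.matrix(X), probability = TRUE)
      unname(attr(pr, "probabilities")[, "wet"])
    },
    neural_net = as.numeric(predict(backend$fit, as.matrix(X))),
    naive_bayes = unname(predict(backend$fit, X, type = "raw")[, "wet"]))
}

feature_columns <- function(table, label_col = "binary_label",
                            exclude = c("plot_id", "x", "y",
                                        "moisture_class")) {
  setdiff(names(table)[vapply(table, is.numeric, TRUE)],
          c(label_col, exclude))
}

#' Tune and train a classifier by grid search with cross-validation
#'
#' For every hyperparameter combination in the grid, the mean Cohen's
#' kappa over `cv_folds` cross-validation folds is computed; the best
#' combination is refit on all training rows.  If a fold happens to miss
#' one of the two classes, folds are redrawn with a shifted seed (logged
#' via `message()`).
#'
#' @param train Training data frame with a `binary_label` factor column
#'   (levels `dry`, `wet`) and numeric feature columns.
#' @param spec A [train_spec].
#' @return A `trained_classifier`: the fitted backend, chosen
#'   hyperparameters, ordered feature names, class order, and the full CV
#'   table (`cv_table`) for audit.
#' @export
tune_and_train <- function(train, spec) {
  if (!inherits(spec, "train_spec")) stop("spec must be a train_spec")
  if (!"binary_label" %in% names(train)) stop("train must have a binary_label column")
  y <- factor(train$binary_label, levels = c("dry", "wet"))
  feats <- feature_columns(train)
  if (length(feats) == 0L) stop("no numeric feature columns found")
  X <- train[feats]
  n <- nrow(X)
  k <- min(spec$cv_folds, n)

  folds <- NULL
  for (attempt in 0:9) {
    set.seed(spec$seed + attempt)
    cand <- sample(rep_len(seq_len(k), n))
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[cand != f])) == 2L, TRUE))
    if (ok) { folds <- cand; break }
    message("fold ", attempt + 1, " missing a class; re-folding with a new seed")
  }
  if (is.null(folds)) stop("could not build folds containing both classes")

  grid <- spec$grid
  cv_kappa <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    ks <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      backend <- fit_one(spec$learner, grid[gidx, , drop = FALSE],
                         X[tr, , drop = FALSE], y[tr], spec$seed + f)
      p <- predict_prob_wet(backend, X[!tr, , drop = FALSE])
      pred <- factor(ifelse(p >= 0.5, "wet", "dry"), levels = c("dry", "wet"))
      ks[f] <- cohen_kappa(table(observed = y[!tr], predicted = pred))
    }
    cv_kappa[gidx] <- mean(ks)
  }
  best <- which.max(cv_kappa)
  backend <- fit_one(spec$learner, grid[best, , drop = FALSE], X, y, spec$seed)
  structure(list(learner = spec$learner,
                 hyperparameters = as.list(grid[best, , drop = FALSE]),
                 backend = backend, feature_names = feats,
                 class_order = c("dry", "wet"),
                 cv_table = cbind(grid, cv_kappa = cv_kappa),
                 seed = spec$seed),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("trained_classifier:", x$learner, "\n")
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = " = ", collapse = ", "), "\n")
  cat("  features (", length(x$feature_names), "): ",
      paste(utils::head(x$feature_names, 6), collapse = ", "),
      if (length(x$feature_names) > 6) ", ..." else "", "\n", sep = "")
  cat("  best CV kappa:", sprintf("%.3f", max(x$cv_table$cv_kappa)), "\n")
  invisible(x)
}

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' observed agreement \eqn{p_o} the normalized trace and expected
#' agreement \eqn{p_e = \sum_i row_i \cdot col_i / N^2}.
#'
#' @param confusion 2x2 matrix of counts, observed classes in rows and
#'   predicted classes in columns (same class order).
#' @return Kappa in `[-1, 1]`; perfect agreement gives 1, agreement at
#'   chance level gives 0.
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (!all(dim(m) == c(2L, 2L))) stop("confusion must be a 2x2 matrix of counts")
  n <- sum(m)
  if (n == 0) stop("confusion matrix is empty")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Build an evaluation report from a confusion matrix
#'
#' @param confusion 2x2 count matrix, rows = observed (`dry`, `wet`),
#'   columns = predicted.
#' @return An `evaluation_report`: confusion counts, overall accuracy (%),
#'   accuracy on wet plots (% of observed-wet classified wet), accuracy on
#'   dry plots, and Cohen's kappa.
#' @export
evaluation_report <- function(confusion) {
  m <- as.matrix(confusion)
  structure(list(
    confusion = m,
    overall_accuracy = 100 * sum(diag(m)) / sum(m),
    accuracy_wet = 100 * m["wet", "wet"] / sum(m["wet", ]),
    accuracy_dry = 100 * m["dry", "dry"] / sum(m["dry", ]),
    kappa = cohen_kappa(m)), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  print(x$confusion)
  cat(sprintf("  overall accuracy: %.1f%%\n", x$overall_accuracy))
  cat(sprintf("  accuracy \"wet\":   %.1f%%\n", x$accuracy_wet))
  cat(sprintf("  accuracy \"dry\":   %.1f%%\n", x$accuracy_dry))
  cat(sprintf("  Cohen's kappa:    %.3f\n", x$kappa))
  invisible(x)
}

#' Evaluate a trained classifier on a test table
#'
#' Predictions are thresholded at P(wet) >= 0.5 and crossed with the
#' observed binary labels.
#'
#' @param model A [tune_and_train()] result.
#' @param test Test data frame containing the model's feature columns and
#'   `binary_label`.
#' @return An [evaluation_report()].
#' @export
evaluate_classifier <- function(model, test) {
  if (!inherits(model, "trained_classifier"))
    stop("model must be a trained_classifier")
  y <- factor(test$binary_label, levels = c("dry", "wet"))
  p <- predict_prob_wet(model$backend, test[model$feature_names])
  pred <- factor(ifelse(p >= 0.5, "wet", "dry"), levels = c("dry", "wet"))
  evaluation_report(table(observed = y, predicted = pred))
}

#' Permutation importance
#'
#' For each feature, the drop in overall accuracy when that column is
#' randomly shuffled, averaged over `n_repeats` shuffles.  Features whose
#' destruction hurts accuracy most rank first.
#'
#' @param model A `trained_classifier`.
#' @param data Data frame with the model's features and `binary_label`.
#' @param n_repeats Shuffles per feature (default 5).
#' @param seed Integer seed.
#' @return Data frame `feature`, `mean_drop`, `sd_drop`, sorted by
#'   decreasing mean accuracy drop.
#' @export
permutation_importance <- function(model, data, n_repeats = 5, seed = 1L) {
  if (!inherits(model, "trained_classifier"))
    stop("model must be a trained_classifier")
  y <- factor(data$binary_label, levels = c("dry", "wet"))
  X <- data[model$feature_names]
  base_acc <- mean((predict_prob_wet(model$backend, X) >= 0.5) == (y == "wet"))
  set.seed(seed)
  drops <- sapply(model$feature_names, function(f) {
    replicate(n_repeats, {
      Xp <- X
      Xp[[f]] <- sample(Xp[[f]])
      base_acc - mean((predict_prob_wet(model$backend, Xp) >= 0.5) == (y == "wet"))
    })
  })
  drops <- matrix(drops, nrow = n_repeats)
  out <- data.frame(feature = model$feature_names,
                    mean_drop = colMeans(drops),
                    sd_drop = apply(drops, 2L, sd))
  out <- out[order(-out$mean_drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict wet probability and class rasters from a layer stack
#'
#' Assembles a per-cell feature matrix from the named layers (in the
#' model's stored feature order), predicts P(wet), and thresholds it at
#' 50 %.  Cells with nodata in any layer propagate nodata.
#'
#' @param model A `trained_classifier`.
#' @param layers Named list of aligned [raster_grid]s covering all model
#'   features.
#' @return List with `class` (boolean [raster_grid], 1 = wet) and
#'   `probability` ([raster_grid] of P(wet) in percent, 0-100).
#' @export
predict_map <- function(model, layers) {
  if (!inherits(model, "trained_classifier"))
    stop("model must be a trained_classifier")
  missing <- setdiff(model$feature_names, names(layers))
  if (length(missing))
    stop("layers missing model features: ", paste(missing, collapse = ", "))
  ref <- layers[[model$feature_names[1L]]]
  X <- as.data.frame(lapply(layers[model$feature_names],
                            function(g) as.vector(g$values)),
                     optional = TRUE)
  ok <- stats::complete.cases(X)
  p <- rep(NA_real_, nrow(X))
  if (any(ok)) p[ok] <- predict_prob_wet(model$backend, X[ok, , drop = FALSE])
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  prob <- rg_like(ref, matrix(100 * p, nr, nc))
  cls <- rg_like(ref, matrix((p >= 0.5) + 0, nr, nc))
  list(class = cls, probability = prob)
}
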