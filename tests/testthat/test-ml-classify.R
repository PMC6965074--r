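# shared tiny separable fixture: label is a deterministic threshold of one
# feature, plus a pure-noise feature
separable_table <- function(n = 200, seed = 5) {
  set.seed(seed)
  d <- runif(n, 0, 6)
  data.frame(dtw = d, noise = rnorm(n),
             binary_label = factor(ifelse(d < 2, "wet", "dry"),
                                   levels = c("dry", "wet")))
}

test_that("train/test split is disjoint, exhaustive and seed-reproducible", {
  tab <- separable_table(100)
  sp <- split_train_test(tab, 0.75, seed = 3)
  expect_equal(nrow(sp$train), 75L)
  expect_equal(nrow(sp$test), 25L)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(tab)))
  sp2 <- split_train_test(tab, 0.75, seed = 3)
  expect_identical(sp$train, sp2$train)
  expect_false(identical(split_train_test(tab, 0.75, seed = 4)$train, sp$train))
})

test_that("a one-point grid is chosen and tuning is deterministic", {
  tab <- separable_table(120)
  spec1 <- train_spec("random_forest", grid = data.frame(mtry = 2), seed = 9)
  m1 <- tune_and_train(tab, spec1)
  expect_equal(m1$hyperparameters$mtry, 2)
  spec2 <- train_spec("naive_bayes", seed = 9)
  m2a <- tune_and_train(tab, spec2)
  m2b <- tune_and_train(tab, spec2)
  expect_identical(m2a$hyperparameters, m2b$hyperparameters)
  expect_identical(m2a$cv_table, m2b$cv_table)
})

test_that("all four learner families achieve near-perfect kappa on separable data", {
  tab <- separable_table(300)
  sp <- split_train_test(tab, 0.75, seed = 1)
  small_grids <- list(
    random_forest = data.frame(mtry = c(1, 2)),
    svm_rbf = expand.grid(cost = c(1, 10), gamma = c(0.1, 1)),
    neural_net = expand.grid(size = 5, decay = c(0, 0.01)),
    naive_bayes = data.frame(laplace = 0))
  for (ln in names(small_grids)) {
    m <- tune_and_train(sp$train, train_spec(ln, grid = small_grids[[ln]],
                                             seed = 2))
    rep <- evaluate_classifier(m, sp$test)
    expect_gt(rep$kappa, 0.85)
    expect_gt(max(m$cv_table$cv_kappa), 0.85)
  }
})

test_that("Cohen's kappa matches its definition and known fixed points", {
  expect_equal(cohen_kappa(matrix(c(50, 0, 0, 50), 2, 2)), 1)   # perfect
  # constant prediction: observed agreement equals chance agreement
  expect_equal(cohen_kappa(matrix(c(60, 40, 0, 0), 2, 2)), 0)
  # literal re-derivation from the definition, independent arithmetic
  set.seed(77)
  for (i in 1:20) {
    m <- matrix(sample(0:200, 4, replace = TRUE), 2, 2)
    if (sum(m) == 0) next
    N <- sum(m)
    po <- (m[1, 1] + m[2, 2]) / N
    pe <- ((m[1, 1] + m[1, 2]) * (m[1, 1] + m[2, 1]) +
           (m[2, 1] + m[2, 2]) * (m[1, 2] + m[2, 2])) / N^2
    if (pe == 1) next
    expect_equal(cohen_kappa(m), (po - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("evaluation reports match a manual confusion tally", {
  obs <- factor(c(rep("wet", 8), rep("dry", 12)), levels = c("dry", "wet"))
  prd <- obs
  prd[c(1, 2, 9)] <- c("dry", "dry", "wet")  # 2 wet and 1 dry misclassified
  rep <- evaluation_report(table(observed = obs, predicted = prd))
  expect_equal(rep$overall_accuracy, 100 * 17 / 20)
  expect_equal(rep$accuracy_wet, 100 * 6 / 8)
  expect_equal(rep$accuracy_dry, 100 * 11 / 12)
  expect_equal(rep$kappa, cohen_kappa(matrix(c(11, 1, 2, 6), 2, 2,
                                             byrow = TRUE)))
  # an all-correct test set scores 100/100/100 and kappa 1
  perfect <- evaluation_report(table(observed = obs, predicted = obs))
  expect_equal(c(perfect$overall_accuracy, perfect$accuracy_wet,
                 perfect$accuracy_dry, perfect$kappa), c(100, 100, 100, 1))
})

test_that("permutation importance separates signal from noise", {
  tab <- separable_table(400)
  m <- tune_and_train(tab, train_spec("random_forest",
                                      grid = data.frame(mtry = 1), seed = 3))
  imp1 <- permutation_importance(m, tab, n_repeats = 5, seed = 11)
  expect_equal(imp1$feature[1], "dtw")     # label-defining feature first
  noise_row <- imp1[imp1$feature == "noise", ]
  expect_lt(abs(noise_row$mean_drop), 2 * max(noise_row$sd_drop, 0.005))
  imp2 <- permutation_importance(m, tab, n_repeats = 5, seed = 11)
  expect_identical(imp1, imp2)             # seed reproducibility
})

test_that("predicted maps are the thresholded probability surface", {
  tab <- separable_table(300)
  m <- tune_and_train(tab, train_spec("random_forest",
                                      grid = data.frame(mtry = 1), seed = 4))
  # constant layers give constant outputs
  lyr <- list(dtw = raster_grid(matrix(0.5, 5, 5), 2),
              noise = raster_grid(matrix(0, 5, 5), 2))
  mp <- predict_map(m, lyr)
  expect_equal(length(unique(as.vector(mp$probability$values))), 1L)
  expect_true(all(mp$class$values == 1))   # dtw 0.5 < 2 is wet
  # varying layer: class raster is exactly probability >= 50
  lyr2 <- list(dtw = raster_grid(matrix(seq(0, 6, length.out = 25), 5, 5), 2),
               noise = raster_grid(matrix(0, 5, 5), 2))
  mp2 <- predict_map(m, lyr2)
  expect_equal(mp2$class$values, (mp2$probability$values >= 50) + 0)
  # nodata propagates
  lyr2$dtw$values[3, 3] <- NA
  mp3 <- predict_map(m, lyr2)
  expect_true(is.na(mp3$probability$values[3, 3]) && is.na(mp3$class$values[3, 3]))
})

test_that("predicted wet probability is calibrated against observed wetness", {
  run <- demo_run()
  m <- run$models$random_forest
  test <- run$split$test
  p <- wetmapr:::predict_prob_wet(m$backend, test[m$feature_names])
  bins <- cut(p, c(-0.01, 0.2, 0.4, 0.6, 0.8, 1.01))
  obs_rate <- tapply(test$binary_label == "wet", bins, mean)
  obs_rate <- obs_rate[!is.na(obs_rate)]
  expect_true(all(diff(obs_rate) > -0.05))  # monotone non-decreasing (slack)
  # mean P(wet) decreases across increasing DTW bins on the landscape
  dtw_bins <- cut(test$DTW_0_5, c(-0.01, 1, 3, 6, Inf))
  mean_p <- tapply(p, dtw_bins, mean)
  expect_true(all(diff(mean_p) < 0))
})
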