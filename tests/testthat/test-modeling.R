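test_that("stratified folds partition 131 subjects into 27+4x26", {
  y <- factor(c(rep("CON", 55), rep("CI", 76)))
  fold <- make_folds(y, 5, seed = 1)
  expect_equal(sort(as.integer(table(fold)), decreasing = TRUE),
               c(27L, 26L, 26L, 26L, 26L))
  # partition property: every subject in exactly one fold
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, 131)
  # stratification: per-fold CI counts within 1 of 76/5
  ci_per_fold <- table(fold[y == "CI"])
  expect_true(all(abs(ci_per_fold - 76 / 5) <= 1))
  # determinism
  expect_identical(fold, make_folds(y, 5, seed = 1))
  expect_false(identical(fold, make_folds(y, 5, seed = 2)))
  expect_error(make_folds(factor(rep(c("CON", "CI"), c(3, 40))), 5),
               "at least 5")
})

test_that("metrics match the hand-computed confusion matrix", {
  # TP=3 FP=1 TN=5 FN=1
  y_true <- c(rep("CI", 4), rep("CON", 6))
  y_pred <- c("CI", "CI", "CI", "CON", "CI", rep("CON", 5))
  score <- c(.9, .8, .7, .3, .6, .4, .3, .2, .1, .05)
  m <- compute_metrics(y_true, y_pred, score)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)

  perfect <- compute_metrics(y_true, y_true, ifelse(y_true == "CI", 1, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1",
                                "auc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, auc = 1))

  expect_equal(compute_metrics(y_true, y_true, rep(0.5, 10))$auc, 0.5)
  expect_warning(m0 <- compute_metrics(y_true, rep("CON", 10), score),
                 "precision undefined")
  expect_equal(m0$precision, 0)
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (r in 1:5) {
    y <- factor(sample(c("CON", "CI"), 40, TRUE), levels = c("CON", "CI"))
    s <- round(rnorm(40), 1)        # ties included
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          levels = c("CON", "CI"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(y, s), ref, tolerance = 1e-10)
  }
})

test_that("label swap maps AUC to its complement", {
  set.seed(22)
  y <- factor(sample(c("CON", "CI"), 60, TRUE), levels = c("CON", "CI"))
  s <- rnorm(60)
  y_flip <- factor(ifelse(y == "CI", "CON", "CI"), levels = c("CON", "CI"))
  expect_equal(roc_auc(y_flip, s), 1 - roc_auc(y, s), tolerance = 1e-12)
})

test_that("both algorithms separate a linearly separable toy problem", {
  sep <- make_separable_table(n_per_class = 20)
  for (alg in c("adaboost_svm", "gbdt")) {
    params <- if (alg == "adaboost_svm")
      list(n_estimators = 10, learning_rate = 0.5, C = 4, gamma = 0.5)
    else
      list(n_estimators = 50, learning_rate = 0.3, subsample = 1,
           max_depth = 3, max_leaf_nodes = 10)
    fit <- fit_ensemble(sep$x, sep$y, alg, params = params, seed = 5)
    expect_equal(mean(predict(fit, sep$x) == sep$y), 1)
    # decision scores order the classes
    expect_equal(roc_auc(sep$y, predict(fit, sep$x, type = "score")), 1)
  }
})

test_that("fitting and grid search are deterministic under a fixed seed", {
  sep <- make_separable_table(n_per_class = 15, gap = 2, seed = 9)
  grid <- expand.grid(n_estimators = c(5L, 10L), learning_rate = 0.5,
                      C = c(1, 16), gamma = 0.5)
  g1 <- grid_search_fit(sep$x, sep$y, "adaboost_svm", grid = grid,
                        n_inner = 3, seed = 7)
  g2 <- grid_search_fit(sep$x, sep$y, "adaboost_svm", grid = grid,
                        n_inner = 3, seed = 7)
  expect_identical(g1$best_params, g2$best_params)
  expect_equal(g1$cv_accuracy, g2$cv_accuracy, tolerance = 1e-12)
  expect_equal(predict(g1$model, sep$x, type = "score"),
               predict(g2$model, sep$x, type = "score"),
               tolerance = 1e-12)
  expect_error(grid_search_fit(sep$x, sep$y, "gbdt", grid = grid[0, ]),
               "empty")
})

test_that("cross_validate reports means equal to fold averages", {
  set.seed(23)
  cfg <- cohort_config(n_con = 15, n_ci = 15, seed = 23)
  coh <- generate_plv_cohort(cfg, n_epochs = 60)
  tab <- select_top_k(fisher_score(coh$table), coh$table, 20)
  grid <- expand.grid(n_estimators = 30L, learning_rate = 0.3,
                      subsample = 0.8, max_depth = 3L,
                      max_leaf_nodes = 10L)
  rep1 <- cross_validate(tab, algorithm = "gbdt", grid = grid,
                         n_inner = 3, seed = 4)
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$per_fold), 5)
  expect_equal(unname(rep1$mean_row),
               unname(colMeans(rep1$per_fold[, -1])), tolerance = 1e-12)
  expect_true(all(rep1$per_fold$accuracy >= 0 &
                  rep1$per_fold$accuracy <= 1))
  # byte-identical reproduction under the same (data, seed) pair
  rep2 <- cross_validate(tab, algorithm = "gbdt", grid = grid,
                         n_inner = 3, seed = 4)
  expect_identical(rep1$per_fold, rep2$per_fold)
})

test_that("per-fold selection keeps feature screening inside each fold", {
  set.seed(24)
  cfg <- cohort_config(n_con = 12, n_ci = 12, seed = 24)
  coh <- generate_plv_cohort(cfg, n_epochs = 60)
  grid <- expand.grid(n_estimators = 30L, learning_rate = 0.3,
                      subsample = 0.8, max_depth = 3L,
                      max_leaf_nodes = 10L)
  rep_lf <- cross_validate(coh$table, algorithm = "gbdt", grid = grid,
                           n_inner = 3, select_k = 20, seed = 6)
  expect_equal(nrow(rep_lf$per_fold), 5)
  expect_true(all(is.finite(rep_lf$per_fold$auc)))
})

test_that("cv report files are written in table layout", {
  sep <- make_separable_table()
  tab <- data.frame(subject_id = paste0("S", 1:40), group = sep$y, sep$x)
  class(tab) <- c("subject_table", "data.frame")
  grid <- expand.grid(n_estimators = 20L, learning_rate = 0.3,
                      subsample = 1, max_depth = 3L, max_leaf_nodes = 10L)
  rep1 <- cross_validate(tab, algorithm = "gbdt", grid = grid,
                         n_inner = 3, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep1, csv, js)
  out <- read.csv(csv)
  expect_equal(out$row, c(paste0("fold", 1:5), "mean"))
  expect_equal(out$accuracy[6], round(rep1$mean_row[["accuracy"]] * 100, 2))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$algorithm, "gbdt")
})
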