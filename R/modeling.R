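# internal: run code under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified fold assignment for cross-validation
#'
#' Partitions subjects into `n_folds` disjoint test folds, stratified by
#' class so per-fold class proportions are within one subject of the
#' global proportions.  Deterministic for a fixed `(y, seed)` pair.
#'
#' @param y class factor (or a `subject_table`, whose `group` column is
#'   used).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..n_folds), one per subject.
#' @export
make_folds <- function(y, n_folds = 5, seed = 1) {
  if (inherits(y, "data.frame")) y <- table_xy(y)$y
  y <- factor(y)
  if (any(tabulate(y) < n_folds))
    stop("each class needs at least ", n_folds, " subjects")
  fold <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      # round-robin over shuffled class members: fold sizes differ by <= 1
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Classification metrics with CI as the positive class
#'
#' Standard definitions: accuracy (TP+TN)/n, precision TP/(TP+FP), recall
#' TP/(TP+FN), F1 their harmonic mean, and AUC as the trapezoidal area
#' under the ROC curve of `y_score` over all thresholds.  An undefined
#' precision (no positive predictions) is reported as 0 with a
#' `precision_undefined` flag.
#'
#' @param y_true,y_pred factors/characters with levels CON/CI.
#' @param y_score numeric score, larger = more CI-like (used for AUC).
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   logical `precision_undefined`.
#' @export
compute_metrics <- function(y_true, y_pred, y_score) {
  y_true <- factor(y_true, levels = c("CON", "CI"))
  y_pred <- factor(y_pred, levels = c("CON", "CI"))
  stopifnot(length(y_true) == length(y_pred),
            length(y_true) == length(y_score))
  tp <- sum(y_pred == "CI" & y_true == "CI")
  fp <- sum(y_pred == "CI" & y_true == "CON")
  tn <- sum(y_pred == "CON" & y_true == "CON")
  fn <- sum(y_pred == "CON" & y_true == "CI")
  acc <- (tp + tn) / length(y_true)
  undef <- (tp + fp) == 0
  if (undef) warning("precision undefined (no positive predictions); ",
                     "reported as 0")
  prec <- if (undef) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       auc = roc_auc(y_true, y_score), precision_undefined = undef)
}

#' Trapezoidal ROC AUC
#'
#' Area under the ROC curve of a score for the CI class, by the trapezoid
#' rule over all score thresholds (ties grouped).  A constant score gives
#' the chance value 0.5.
#'
#' @param y_true factor/character with levels CON/CI.
#' @param y_score numeric score, larger = more CI-like.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, y_score) {
  y <- factor(y_true, levels = c("CON", "CI"))
  pos <- sum(y == "CI"); neg <- sum(y == "CON")
  if (pos == 0 || neg == 0) return(NA_real_)
  ord <- order(y_score, decreasing = TRUE)
  ys <- y_score[ord]; lab <- y[ord]
  # group tied scores: one ROC vertex per distinct threshold
  grp <- cumsum(!duplicated(ys))
  tp <- tapply(lab == "CI", grp, sum)
  fp <- tapply(lab == "CON", grp, sum)
  tpr <- c(0, cumsum(tp) / pos)
  fpr <- c(0, cumsum(fp) / neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Hyperparameter grids for the two ensemble algorithms
#'
#' Discretizations of the published search ranges: AdaBoost-SVM --
#' n_estimators 50-150, learning_rate (0,1], C 2^-10..2^10, gamma
#' 1e-4..10; GBDT -- n_estimators 50-150, learning_rate (0,1], subsample
#' 0.5-0.8, max_depth (including 8) and max_leaf_nodes 10-30.  `reduced =
#' TRUE` gives a small grid for desk-scale experiments and tests.
#'
#' @param algorithm `"adaboost_svm"` or `"gbdt"`.
#' @param reduced use the small grid (default `FALSE`).
#' @return data.frame, one row per hyperparameter combination.
#' @export
default_grid <- function(algorithm = c("adaboost_svm", "gbdt"),
                         reduced = FALSE) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "adaboost_svm") {
    if (reduced)
      expand.grid(n_estimators = c(20L, 40L), learning_rate = c(0.3, 1),
                  C = c(1, 64), gamma = c(0.01, 0.25))
    else
      expand.grid(n_estimators = c(50L, 75L, 100L, 125L, 150L),
                  learning_rate = seq(0.1, 1, by = 0.1),
                  C = 4^(-5:5), gamma = 10^seq(-4, 1))
  } else {
    if (reduced)
      expand.grid(n_estimators = c(50L, 100L), learning_rate = c(0.1, 0.3),
                  subsample = c(0.7, 0.8), max_depth = c(3L, 8L),
                  max_leaf_nodes = c(10L, 15L))
    else
      expand.grid(n_estimators = c(50L, 75L, 100L, 125L, 150L),
                  learning_rate = seq(0.1, 1, by = 0.1),
                  subsample = c(0.5, 0.6, 0.7, 0.8),
                  max_depth = c(8L, 10L, 12L, 15L),
                  max_leaf_nodes = c(10L, 15L, 20L, 25L, 30L))
  }
}

# ---- AdaBoost with RBF-SVM base learner (SAMME.R) -------------------------

# internal: one SAMME.R fit.  e1071::svm takes no per-sample weights, so
# each boosting round fits the base SVM on a weighted bootstrap resample;
# class-probability estimates (Platt calibration, probability = TRUE) on
# the full training set drive the real-valued SAMME.R weight update.
adaboost_svm_fit <- function(x, y, n_estimators = 50, learning_rate = 1,
                             C = 1, gamma = 1 / ncol(x), seed = 1) {
  n <- nrow(x); K <- 2L
  lev <- levels(y)
  w <- rep(1 / n, n)
  eps <- 1e-10
  models <- vector("list", n_estimators)
  ycode <- matrix(-1, n, K)           # SAMME.R coding: 1 for own class
  ycode[cbind(seq_len(n), as.integer(y))] <- 1
  used <- 0L
  with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      idx <- NULL
      for (try in 1:50) {
        idx <- sample.int(n, n, replace = TRUE, prob = w)
        if (length(unique(y[idx])) == 2) break
      }
      fit <- e1071::svm(x[idx, , drop = FALSE], y[idx], kernel = "radial",
                        cost = C, gamma = gamma, probability = TRUE,
                        scale = FALSE)
      pr <- attr(stats::predict(fit, x, probability = TRUE),
                 "probabilities")[, lev, drop = FALSE]
      pr <- pmin(pmax(pr, eps), 1 - eps)
      yhat <- lev[max.col(pr)]
      err <- sum(w * (yhat != y))
      models[[m]] <- fit
      used <- m
      if (err <= 0) break             # perfect fit: stop boosting
      # w_i *= exp(-lr * (K-1)/K * sum_k ycode_ik log p_ik)
      expo <- -learning_rate * ((K - 1) / K) * rowSums(ycode * log(pr))
      w <- w * exp(expo)
      w <- w / sum(w)
    }
  })
  structure(list(models = models[seq_len(used)], levels = lev,
                 learning_rate = learning_rate, C = C, gamma = gamma,
                 n_estimators = n_estimators, seed = seed),
            class = "adaboost_svm")
}

# internal: SAMME.R decision score for the CI class (sum over estimators
# of (K-1) * (log p_k - mean_k log p))
adaboost_svm_score <- function(object, x) {
  eps <- 1e-10
  score <- numeric(nrow(x))
  for (fit in object$models) {
    pr <- attr(stats::predict(fit, x, probability = TRUE),
               "probabilities")[, object$levels, drop = FALSE]
    pr <- log(pmin(pmax(pr, eps), 1 - eps))
    h <- pr - rowMeans(pr)            # (K-1) = 1 for two classes
    score <- score + h[, "CI"]
  }
  score
}

# ---- shared fitted-model interface ---------------------------------------

#' Fit a boosted ensemble classifier
#'
#' The two diagnostic-model algorithms: `"adaboost_svm"` is AdaBoost
#' (SAMME.R variant) over RBF-kernel SVM base learners with Platt
#' probability calibration; `"gbdt"` is a gradient-boosted ensemble of
#' binary decision (CART) trees.  Features are standardized internally
#' (zero-variance columns left unscaled); CI is the positive class.
#'
#' @param x numeric feature matrix (subjects x features) or a
#'   `subject_table`.
#' @param y class factor with levels CON/CI (ignored when `x` is a
#'   `subject_table`).
#' @param algorithm `"adaboost_svm"` or `"gbdt"`.
#' @param params named list of hyperparameters (one row of
#'   [default_grid()]): for AdaBoost `n_estimators`, `learning_rate`, `C`,
#'   `gamma`; for GBDT `n_estimators`, `learning_rate`, `subsample`,
#'   `max_depth`, `max_leaf_nodes`.
#' @param seed integer seed controlling all fitting randomness.
#' @return A `plv_ensemble` object with `predict`, `print` and `summary`
#'   methods.
#' @export
fit_ensemble <- function(x, y = NULL,
                         algorithm = c("adaboost_svm", "gbdt"),
                         params = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  if (inherits(x, "data.frame")) {
    xy <- table_xy(x); x <- xy$x; y <- xy$y
  }
  y <- factor(y, levels = c("CON", "CI"))
  if (nlevels(droplevels(y)) != 2) stop("training data needs both classes")

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)

  p <- params
  if (algorithm == "adaboost_svm") {
    fit <- adaboost_svm_fit(
      xs, y,
      n_estimators = p$n_estimators %||% 50,
      learning_rate = p$learning_rate %||% 1,
      C = p$C %||% 1, gamma = p$gamma %||% (1 / ncol(xs)),
      seed = seed)
  } else {
    dtrain <- xgboost::xgb.DMatrix(xs, label = as.integer(y == "CI"))
    xgp <- list(objective = "binary:logistic",
                eta = p$learning_rate %||% 0.3,
                max_depth = as.integer(p$max_depth %||% 6),
                subsample = p$subsample %||% 1,
                max_leaves = as.integer(p$max_leaf_nodes %||% 0),
                grow_policy = "lossguide", tree_method = "hist",
                nthread = 1, seed = seed)
    fit <- xgboost::xgb.train(params = xgp, data = dtrain,
                              nrounds = as.integer(p$n_estimators %||% 100),
                              verbose = 0)
  }
  structure(list(algorithm = algorithm, fit = fit, params = p,
                 center = ctr, scale = scl,
                 feature_names = colnames(x), seed = seed,
                 n_train = nrow(x)),
            class = "plv_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a fitted ensemble
#'
#' @param object a `plv_ensemble` from [fit_ensemble()].
#' @param newdata feature matrix or `subject_table` with the training
#'   columns.
#' @param type `"class"` (CON/CI factor), `"score"` (real decision score,
#'   larger = more CI-like) or `"prob"` (probability of CI; for AdaBoost a
#'   logistic squash of the decision score).
#' @param ... unused.
#' @return Vector of predictions.
#' @export
predict.plv_ensemble <- function(object, newdata,
                                 type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "data.frame")) newdata <- table_xy(newdata)$x
  newdata <- newdata[, object$feature_names, drop = FALSE]
  xs <- scale(newdata, center = object$center, scale = object$scale)
  if (object$algorithm == "adaboost_svm") {
    score <- adaboost_svm_score(object$fit, xs)
    prob <- 1 / (1 + exp(-2 * score / max(1, length(object$fit$models))))
  } else {
    prob <- stats::predict(object$fit, xgboost::xgb.DMatrix(xs))
    score <- prob
  }
  switch(type,
         score = score,
         prob = prob,
         class = factor(ifelse(score > if (object$algorithm == "gbdt") 0.5
                               else 0, "CI", "CON"),
                        levels = c("CON", "CI")))
}

#' @export
print.plv_ensemble <- function(x, ...) {
  cat(sprintf("<plv_ensemble> %s fitted on %d subjects x %d features\n",
              x$algorithm, x$n_train, length(x$feature_names)))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.plv_ensemble <- function(object, ...) {
  print(object)
  cat("  seed:", object$seed, "\n")
  invisible(object)
}

# ---- grid search and cross-validation ------------------------------------

#' Grid search with internal cross-validation
#'
#' Exhaustive search over a hyperparameter grid, scoring each combination
#' by mean accuracy under internal stratified k-fold cross-validation on
#' the training split, then refitting the best combination (first row wins
#' ties) on the full split.
#'
#' @param x feature matrix or `subject_table` (training split).
#' @param y class factor when `x` is a matrix.
#' @param algorithm `"adaboost_svm"` or `"gbdt"`.
#' @param grid data.frame of combinations, as from [default_grid()].
#' @param n_inner internal folds (default 5).
#' @param seed integer seed.
#' @return List: `model` (refitted `plv_ensemble`), `best_params` (named
#'   list), `cv_accuracy` (vector of per-combination mean accuracies).
#' @export
grid_search_fit <- function(x, y = NULL,
                            algorithm = c("adaboost_svm", "gbdt"),
                            grid = default_grid(algorithm, reduced = TRUE),
                            n_inner = 5, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (inherits(x, "data.frame")) { xy <- table_xy(x); x <- xy$x; y <- xy$y }
  y <- factor(y, levels = c("CON", "CI"))
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  fold <- make_folds(y, n_folds = n_inner, seed = seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- as.list(grid[g, , drop = FALSE])
    fold_acc <- vapply(seq_len(n_inner), function(f) {
      tr <- fold != f
      m <- fit_ensemble(x[tr, , drop = FALSE], y[tr], algorithm,
                        params = p, seed = seed + g)
      mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    acc[g] <- mean(fold_acc)
  }
  best <- which.max(acc)              # first max: deterministic tie-break
  model <- fit_ensemble(x, y, algorithm,
                        params = as.list(grid[best, , drop = FALSE]),
                        seed = seed)
  list(model = model, best_params = as.list(grid[best, , drop = FALSE]),
       cv_accuracy = acc)
}

#' Five-fold cross-validated performance report
#'
#' The headline evaluation: stratified k-fold cross-validation where each
#' training split undergoes a (nested) grid search, the held-out fold is
#' predicted, and accuracy, precision, recall, F1 and trapezoidal AUC are
#' computed per fold with CI as the positive class.  The mean row is the
#' arithmetic mean of the fold rows.
#'
#' @param table a `subject_table`, or feature matrix with `y` given.
#' @param y class factor when `table` is a matrix.
#' @param algorithm `"adaboost_svm"` or `"gbdt"`.
#' @param grid hyperparameter grid (default the reduced grid).
#' @param n_folds outer folds (default 5).
#' @param n_inner inner grid-search folds (default 5).
#' @param select_k optional per-fold feature count: when given, a Fisher
#'   ranking is fitted on each training split alone and its top
#'   `select_k` features are used for that fold, keeping selection
#'   leakage-free.  The default `NULL` uses the columns as passed --
#'   screening on the full table before CV mirrors the classical
#'   sequence (ranking precedes model construction) but leaks selection
#'   information across folds and optimistically biases the estimate.
#' @param seed integer seed; a fixed (data, seed) pair reproduces the
#'   report exactly.
#' @return A `cv_report`: list with `per_fold` (data.frame, one row per
#'   fold), `mean_row`, `chosen_params` (per-fold best hyperparameters),
#'   `algorithm`, `seed`.
#' @export
cross_validate <- function(table, y = NULL,
                           algorithm = c("adaboost_svm", "gbdt"),
                           grid = default_grid(algorithm, reduced = TRUE),
                           n_folds = 5, n_inner = 5, select_k = NULL,
                           seed = 1) {
  algorithm <- match.arg(algorithm)
  if (inherits(table, "data.frame")) {
    xy <- table_xy(table); x <- xy$x; y <- xy$y
  } else x <- as.matrix(table)
  y <- factor(y, levels = c("CON", "CI"))
  fold <- make_folds(y, n_folds = n_folds, seed = seed)
  rows <- vector("list", n_folds)
  chosen <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    xf <- x
    if (!is.null(select_k)) {
      rk <- fisher_score(x[tr, , drop = FALSE], y[tr])
      xf <- x[, rk$feature[seq_len(min(select_k, nrow(rk)))],
              drop = FALSE]
    }
    gs <- grid_search_fit(xf[tr, , drop = FALSE], y[tr], algorithm,
                          grid = grid, n_inner = n_inner, seed = seed + f)
    yhat <- predict(gs$model, xf[!tr, , drop = FALSE], type = "class")
    score <- predict(gs$model, xf[!tr, , drop = FALSE], type = "score")
    m <- suppressWarnings(compute_metrics(y[!tr], yhat, score))
    rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1, auc = m$auc)
    chosen[[f]] <- gs$best_params
  }
  per_fold <- do.call(rbind, rows)
  mean_row <- colMeans(per_fold[, -1])
  structure(list(per_fold = per_fold, mean_row = mean_row,
                 chosen_params = chosen, algorithm = algorithm,
                 n_folds = n_folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d-fold CV (seed %d)\n", x$algorithm,
              x$n_folds, x$seed))
  tab <- rbind(x$per_fold[, -1], mean = x$mean_row)
  rownames(tab) <- c(paste("fold", x$per_fold$fold), "mean")
  print(round(tab, 4))
  invisible(x)
}

#' Write a cross-validation report to CSV and JSON
#'
#' CSV rows are fold 1..k plus the mean row (metrics as percentages except
#' AUC, mirroring the usual presentation); JSON captures folds, means,
#' chosen hyperparameters and seed.
#'
#' @param report a `cv_report`.
#' @param path_csv,path_json output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_cv_report <- function(report, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "cv_report"))
  tab <- rbind(report$per_fold[, -1], report$mean_row)
  out <- data.frame(row = c(paste0("fold", report$per_fold$fold), "mean"))
  pct <- c("accuracy", "precision", "recall", "f1")
  out[pct] <- round(tab[pct] * 100, 2)
  out["auc"] <- round(tab["auc"], 4)
  if (!is.null(path_csv)) utils::write.csv(out, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(
      list(algorithm = report$algorithm, seed = report$seed,
           per_fold = report$per_fold, mean = as.list(report$mean_row),
           chosen_params = report$chosen_params),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
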