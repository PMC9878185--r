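#' Fisher score ranking of features
#'
#' For a two-class table, each feature j receives the score
#' \deqn{F_j = \frac{\sum_k n_k (\mu_{jk} - \mu_j)^2}
#'                  {\sum_k n_k \sigma^2_{jk} + \epsilon}}
#' where k runs over the classes, \eqn{\mu_{jk}} and \eqn{\sigma^2_{jk}}
#' are the within-class mean and population variance, \eqn{\mu_j} the
#' overall mean and \eqn{\epsilon = 10^{-12}} guards degenerate
#' denominators.  High scores mean large between-class and small
#' within-class variance.  Scores are scale-invariant per feature.
#'
#' @param table a `subject_table` (see [assemble_table()]), or a numeric
#'   matrix if `y` is given.
#' @param y optional class factor when `table` is a plain matrix.
#' @return A `fisher_ranking`: data.frame with `rank`, `feature`, `score`,
#'   sorted by descending score, ties broken by original column order.
#' @export
fisher_score <- function(table, y = NULL) {
  if (is.null(y)) {
    xy <- table_xy(table)
    x <- xy$x; y <- xy$y
  } else {
    x <- as.matrix(table)
    y <- factor(y)
  }
  y <- droplevels(y)
  if (nlevels(y) != 2)
    stop("fisher_score requires exactly 2 classes, got ", nlevels(y))
  if (any(tabulate(y) < 2)) stop("each class needs at least 2 subjects")
  if (!all(is.finite(x))) stop("all feature values must be finite")

  mu <- colMeans(x)
  num <- den <- numeric(ncol(x))
  for (lev in levels(y)) {
    xk <- x[y == lev, , drop = FALSE]
    nk <- nrow(xk)
    muk <- colMeans(xk)
    vk <- colMeans(xk^2) - muk^2      # population variance
    num <- num + nk * (muk - mu)^2
    den <- den + nk * vk
  }
  score <- num / (den + 1e-12)
  ord <- order(-score)                # stable: ties keep column order
  structure(
    data.frame(rank = seq_along(ord),
               feature = colnames(x)[ord],
               score = score[ord],
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("fisher_ranking", "data.frame"))
}

#' @export
print.fisher_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<fisher_ranking> %d features; top %d:\n", nrow(x),
              min(n, nrow(x))))
  print.data.frame(utils::head(x, n), ...)
  invisible(x)
}

#' Keep the top-k features of a ranking
#'
#' Restricts a subject table to the k highest-scoring feature columns, in
#' ranking order.  Typical configurations: top 15 of the clinical view,
#' top 150 of the PLV view, top 150/250 of the combined view.
#'
#' @param ranking a `fisher_ranking` from [fisher_score()].
#' @param table the `subject_table` the ranking was computed on.
#' @param k number of features to keep, `1 <= k <= n_features`.
#' @return The `subject_table` restricted to `subject_id`, `group` and the
#'   k selected columns.
#' @export
select_top_k <- function(ranking, table, k) {
  stopifnot(inherits(ranking, "fisher_ranking"))
  if (k < 1 || k > nrow(ranking))
    stop("k must be in [1, ", nrow(ranking), "]")
  keep <- ranking$feature[seq_len(k)]
  out <- table[, c(intersect(c("subject_id", "group"), names(table)), keep),
               drop = FALSE]
  class(out) <- class(table)
  attr(out, "view") <- attr(table, "view")
  out
}
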