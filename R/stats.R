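#' Two-group comparison of a single feature
#'
#' Continuous features are first gated by a per-group Shapiro-Wilk
#' normality test at alpha = 0.05: if both groups pass, a two-sided
#' independent-samples t-test (pooled variance) is used, otherwise the
#' two-sided Mann-Whitney U test.  Categorical features use the Pearson
#' chi-square test (no continuity correction), falling back to Fisher's
#' exact test when a 2x2 table has any expected cell count below 5 (for
#' larger sparse tables the chi-square is kept, with a warning).  A
#' feature constant in both groups returns p = 1 with a `degenerate` flag.
#'
#' @param values numeric (continuous) or category vector.
#' @param group two-level factor/character aligned with `values`.
#' @param feature_kind `"continuous"` or `"categorical"`.
#' @param test force `"auto"` (default), or one of `"t"`,
#'   `"mann_whitney"`, `"chi_square"`, `"fisher_exact"`.
#' @return A `comparison_result` list: `test_used`, `statistic`, `p`,
#'   `group_summaries`, `degenerate`.
#' @export
compare_feature <- function(values, group,
                            feature_kind = c("continuous", "categorical"),
                            test = "auto") {
  feature_kind <- match.arg(feature_kind)
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("exactly two groups required")
  g1 <- values[group == levels(group)[1]]
  g2 <- values[group == levels(group)[2]]
  if (length(g1) == 0 || length(g2) == 0) stop("empty group")

  if (feature_kind == "continuous") {
    sm <- lapply(list(g1, g2), function(v)
      c(mean = mean(v), sd = stats::sd(v), n = length(v)))
    names(sm) <- levels(group)
    if (stats::sd(values) == 0)
      return(structure(list(test_used = "t", statistic = 0, p = 1,
                            group_summaries = sm, degenerate = TRUE),
                       class = "comparison_result"))
    normal <- vapply(list(g1, g2), function(v) {
      if (stats::sd(v) == 0 || length(v) < 3) return(FALSE)
      stats::shapiro.test(v)$p.value >= 0.05
    }, logical(1))
    use_t <- if (test == "auto") all(normal) else test == "t"
    if (use_t) {
      ht <- stats::t.test(g1, g2, var.equal = TRUE)
      res <- list(test_used = "t", statistic = unname(ht$statistic),
                  p = ht$p.value)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(g1, g2, exact = TRUE))
      res <- list(test_used = "mann_whitney",
                  statistic = unname(ht$statistic), p = ht$p.value)
    }
  } else {
    tab <- table(group, values)
    sm <- list(counts = tab)
    if (ncol(tab) < 2)
      return(structure(list(test_used = "chi_square", statistic = 0, p = 1,
                            group_summaries = sm, degenerate = TRUE),
                       class = "comparison_result"))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    small <- any(expected < 5)
    use_fisher <- if (test == "auto") small && all(dim(tab) == 2)
                  else test == "fisher_exact"
    if (use_fisher) {
      ht <- stats::fisher.test(tab)
      res <- list(test_used = "fisher_exact", statistic = NA_real_,
                  p = ht$p.value)
    } else {
      if (small && !all(dim(tab) == 2))
        warning("expected counts < 5 in a table larger than 2x2; ",
                "chi-square p may be unreliable")
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      res <- list(test_used = "chi_square",
                  statistic = unname(ht$statistic), p = ht$p.value)
    }
    res$group_summaries <- sm
    res$degenerate <- FALSE
    return(structure(res, class = "comparison_result"))
  }
  res$group_summaries <- sm
  res$degenerate <- FALSE
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %s, p = %.4g%s\n",
              x$test_used,
              ifelse(is.na(x$statistic), "-", format(x$statistic)),
              x$p, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, returned in the
#' original order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pooled mean of group means
#'
#' The sample-size-weighted mean `sum(n_i m_i) / sum(n_i)`, used to check
#' whole-cohort summaries against per-group summaries.
#'
#' @param means group means.
#' @param ns group sizes (positive).
#' @return Scalar pooled mean.
#' @export
pooled_mean <- function(means, ns) {
  if (length(means) == 0 || length(means) != length(ns))
    stop("means and ns must be non-empty and of equal length")
  if (any(ns <= 0)) stop("group sizes must be positive")
  sum(means * ns) / sum(ns)
}

#' Batch group comparison over a feature table
#'
#' Runs [compare_feature()] for every feature column and applies one
#' Benjamini-Hochberg family over the whole batch.
#'
#' @param table a `subject_table` or data.frame with a `group` column.
#' @param kinds named character vector mapping features to
#'   `"continuous"`/`"categorical"`; defaults to `"continuous"` for every
#'   column.
#' @return data.frame with `feature`, `test_used`, `statistic`, `p`,
#'   `p_fdr`.
#' @export
compare_table <- function(table, kinds = NULL) {
  feats <- setdiff(names(table), c("subject_id", "group"))
  if (is.null(kinds)) kinds <- stats::setNames(rep("continuous",
                                                   length(feats)), feats)
  rows <- lapply(feats, function(f) {
    kind <- if (f %in% names(kinds)) kinds[[f]] else "continuous"
    r <- compare_feature(table[[f]], table$group, kind)
    data.frame(feature = f, test_used = r$test_used,
               statistic = r$statistic, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_correct(out$p)
  out
}
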