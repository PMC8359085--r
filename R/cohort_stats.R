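#' Kolmogorov-Smirnov normality screen
#'
#' One-sample two-sided KS test of the values against a normal distribution
#' with the sample mean and standard deviation (no estimated-parameter
#' correction). A constant sample cannot be normal; it returns p = 0 with a
#' warning.
#'
#' @param values Numeric vector, n >= 5.
#' @return Two-sided p-value.
#' @export
normality_test <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) stop("normality screen requires n >= 5")
  s <- stats::sd(values)
  if (s == 0) {
    warning("constant sample: flagged non-normal (p = 0)")
    return(0)
  }
  suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s)$p.value
  )
}

#' Between-group comparison of a continuous feature
#'
#' The univariate machinery of the group-comparison tables: both groups are
#' screened for normality (KS at alpha = 0.05); if both pass, an
#' independent-sample t test is used, otherwise a Mann-Whitney U test —
#' exact by enumeration when the smaller group has at most 10 observations
#' and the pooled values are tie-free, otherwise the tie-corrected normal
#' approximation. Rank means (mid-ranks over the pooled sample) are always
#' reported, alongside group means and medians. All p-values are two-tailed.
#'
#' @param x0,x1 Numeric vectors, the two groups (each n >= 2). By
#'   convention `x0` is the reference (e.g. Un-improved) and `x1` the
#'   positive group (e.g. Improved).
#' @param force_test Optional `"t"` or `"wilcox"` to override the normality
#'   gate.
#' @param feature Optional feature name carried into the result.
#' @return A list of class `group_comparison`: `feature`, `test` ("t" or
#'   "wilcox"), `statistic` (t, or the Mann-Whitney U of group 1),
#'   `p`, `rank_mean` (length 2: group 0, group 1), `mean`, `median`, `n`.
#' @export
compare_groups_continuous <- function(x0, x1, force_test = NULL,
                                      feature = NA_character_) {
  x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
  n0 <- length(x0); n1 <- length(x1)
  if (n0 < 2L || n1 < 2L) stop("each group needs at least 2 observations")
  pooled <- c(x0, x1)
  rk <- rank(pooled)  # mid-ranks for ties
  rank_mean <- c(mean(rk[seq_len(n0)]), mean(rk[n0 + seq_len(n1)]))
  use_t <- if (!is.null(force_test)) {
    match.arg(force_test, c("t", "wilcox")) == "t"
  } else {
    sd0 <- stats::sd(x0); sd1 <- stats::sd(x1)
    sd0 > 0 && sd1 > 0 && n0 >= 5L && n1 >= 5L &&
      normality_test(x0) > 0.05 && normality_test(x1) > 0.05
  }
  if (use_t) {
    ht <- stats::t.test(x1, x0)
    test <- "t"; statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    ties <- anyDuplicated(pooled) > 0L
    exact <- !ties && min(n0, n1) <= 10L
    ht <- suppressWarnings(
      stats::wilcox.test(x1, x0, exact = exact, correct = FALSE)
    )
    test <- "wilcox"; statistic <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(feature = feature, test = test, statistic = statistic,
                 p = min(p, 1),
                 rank_mean = rank_mean,
                 mean = c(mean(x0), mean(x1)),
                 median = c(stats::median(x0), stats::median(x1)),
                 n = c(n0, n1)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %s test: statistic %.4g, p = %.4g\n",
              if (is.na(x$feature)) "" else paste0(" ", x$feature),
              x$test, x$statistic, x$p))
  cat(sprintf("  group 0: n %d, rank mean %.2f, mean/median %.4g/%.4g\n",
              x$n[1], x$rank_mean[1], x$mean[1], x$median[1]))
  cat(sprintf("  group 1: n %d, rank mean %.2f, mean/median %.4g/%.4g\n",
              x$n[2], x$rank_mean[2], x$mean[2], x$median[2]))
  invisible(x)
}

#' Between-group comparison of a categorical variable
#'
#' Chi-squared test without continuity correction when every expected
#' count is at least 5; otherwise Fisher's exact test for 2 x 2 tables.
#' Wider tables with small expected counts fall back to chi-squared with a
#' warning (the exact test is restricted to 2 x 2 here).
#'
#' @param counts A 2 x k contingency table (groups in rows).
#' @return List with `test` ("chisq" or "fisher"), `statistic` (chi-squared
#'   statistic, `NA` for Fisher), and two-tailed `p`.
#' @export
compare_groups_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("counts must have 2 rows (the groups)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("both margins must be positive")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected >= 5)) {
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(test = "chisq", statistic = unname(ht$statistic), p = ht$p.value)
  } else if (ncol(counts) == 2L) {
    ht <- stats::fisher.test(counts)
    list(test = "fisher", statistic = NA_real_, p = ht$p.value)
  } else {
    warning("small expected counts in a 2 x k table (k > 2): ",
            "chi-squared used; treat p with caution")
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(test = "chisq", statistic = unname(ht$statistic), p = ht$p.value)
  }
}

#' Group-comparison table over all texture features
#'
#' Applies [compare_groups_continuous()] to every feature column of a
#' cohort feature table, producing the familiar comparison-table shape:
#' rank means, mean/median per group, the test used, its statistic and the
#' two-tailed p-value. No multiplicity correction is applied.
#'
#' @param features A data frame from [cohort_features()] (or any data frame
#'   with a `group` column of 0/1 and the feature columns).
#' @param feature_names Columns to compare; defaults to the 32-name
#'   catalogue.
#' @return A data frame, one row per feature, ordered as given.
#' @export
compare_feature_table <- function(features,
                                  feature_names = aef_feature_names()) {
  stopifnot(is.data.frame(features), "group" %in% names(features))
  missing_cols <- setdiff(feature_names, names(features))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  rows <- lapply(feature_names, function(f) {
    cmp <- compare_groups_continuous(features[[f]][features$group == 0L],
                                     features[[f]][features$group == 1L],
                                     feature = f)
    data.frame(feature = f, test = cmp$test,
               rank_mean_g1 = cmp$rank_mean[2], rank_mean_g0 = cmp$rank_mean[1],
               mean_g1 = cmp$mean[2], mean_g0 = cmp$mean[1],
               median_g1 = cmp$median[2], median_g0 = cmp$median[1],
               statistic = cmp$statistic, p = cmp$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
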