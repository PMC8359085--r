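#' ROC analysis with optimal-cutoff classification metrics
#'
#' Builds the ROC curve over all distinct score thresholds (predicted
#' positive means score >= threshold), computes the AUC by the trapezoidal
#' rule — identical to the Mann-Whitney rank statistic with mid-rank ties,
#' U / (n0 n1) — and reports accuracy, sensitivity and specificity at the
#' cutoff maximizing Youden's J (sensitivity + specificity - 1); J ties
#' break to the lower cutoff.
#'
#' @param scores Numeric scores (higher means more likely positive).
#' @param labels Binary 0/1 outcome (both classes must be present).
#' @return An object of class `roc_result`: `auc`, `cutoff`, `accuracy`,
#'   `sensitivity`, `specificity`, and `curve` (data frame of `threshold`,
#'   `fpr`, `tpr`, beginning at (0,0) and ending at (1,1)).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  # trapezoid over the curve (last point is always (1,1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[length(best)]  # thresholds descend: last max = lowest cutoff
  cutoff <- thr[best]
  pred <- as.integer(scores >= cutoff)
  structure(list(auc = auc, cutoff = cutoff,
                 accuracy = mean(pred == labels),
                 sensitivity = sum(pred == 1L & labels == 1L) / n1,
                 specificity = sum(pred == 0L & labels == 0L) / n0,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.3f | cutoff %.4g: accuracy %.3f, ",
                     "sensitivity %.3f, specificity %.3f\n"),
              x$auc, x$cutoff, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Calibration curve and recalibration slope
#'
#' Groups predicted probabilities into `n_bins` equal-frequency bins and
#' pairs each bin's mean predicted probability with the observed event
#' fraction. The calibration slope and intercept come from a logistic
#' recalibration of the labels on the linear predictor
#' `logit(probability)`; slope 1, intercept 0 indicates perfect
#' calibration.
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param labels Binary 0/1 outcome (both classes present).
#' @param n_bins Number of equal-frequency bins; must not exceed n/2.
#' @return List with `bins` (data frame of `p_mean`, `obs_fraction`, `n`),
#'   `slope`, `intercept`.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10L) {
  labels <- as.integer(labels)
  n <- length(probabilities)
  if (n_bins > n / 2) stop("n_bins must not exceed half the sample size")
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  if (length(unique(labels)) < 2L) stop("both outcome classes must be present")
  qs <- stats::quantile(probabilities, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  edges <- unique(qs)  # duplicated quantiles collapse degenerate bins
  bin <- if (length(edges) > 1L)
    cut(probabilities, breaks = edges, include.lowest = TRUE)
  else factor(rep(1L, n))
  bins <- do.call(rbind, lapply(split(seq_len(n), bin), function(idx) {
    if (!length(idx)) return(NULL)
    data.frame(p_mean = mean(probabilities[idx]),
               obs_fraction = mean(labels[idx]), n = length(idx))
  }))
  rownames(bins) <- NULL
  eps <- 1e-12
  lp <- stats::qlogis(pmin(pmax(probabilities, eps), 1 - eps))
  fit <- suppressWarnings(
    stats::glm(labels ~ lp, family = stats::binomial())
  )
  list(bins = bins, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Decision curve analysis
#'
#' Net benefit of using the model to decide treatment at each threshold
#' probability pt: `TP/n - (FP/n) * pt / (1 - pt)` with predicted-positive
#' meaning probability >= pt (closed on the left), compared against
#' treating everyone (`prevalence - (1 - prevalence) * pt / (1 - pt)`) and
#' treating no one (identically 0).
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary 0/1 outcome.
#' @param thresholds Threshold grid inside (0, 1); default 0.01 to 0.99 by
#'   0.01.
#' @return An object of class `net_benefit_curve`: data frame with
#'   `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  n <- length(labels)
  prev <- mean(labels)
  nb_model <- vapply(thresholds, function(pt) {
    pos <- probabilities >= pt
    tp <- sum(pos & labels == 1L); fp <- sum(pos & labels == 0L)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- data.frame(threshold = thresholds, nb_model = nb_model,
                    nb_all = nb_all, nb_none = 0)
  class(out) <- c("net_benefit_curve", "data.frame")
  out
}

#' Full model evaluation report
#'
#' ROC analysis, calibration curve and decision curve for one set of
#' predicted probabilities, bundled for serialization.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary 0/1 outcome.
#' @param n_bins Calibration bins.
#' @param thresholds Decision-curve threshold grid.
#' @return List with `roc`, `calibration`, `decision`, and `meta`
#'   (cutoff rule used).
#' @export
evaluate_model <- function(probabilities, labels, n_bins = 10L,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  list(roc = roc_analysis(probabilities, labels),
       calibration = calibration_curve(probabilities, labels,
                                       n_bins = min(n_bins,
                                                    length(labels) %/% 2)),
       decision = decision_curve(probabilities, labels, thresholds),
       meta = list(cutoff_rule = "youden", positive_rule = ">= cutoff"))
}
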