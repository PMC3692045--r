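check_scored_labels <- function(scores, labels, need_neg = TRUE) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)),
            !any(is.na(scores)))
  if (!any(labels > 0)) stop("no positive labels")
  if (need_neg && !any(labels < 0)) stop("no negative labels")
}

# cumulative TP/FP at each distinct score threshold, descending; tied
# scores collapse to one step so tie blocks become single segments
threshold_counts <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; pos <- labels[o] > 0
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie block
  list(tp = cumsum(pos)[last], fp = cumsum(!pos)[last],
       threshold = s[last])
}

#' ROC curve and AUROC
#'
#' Sweeps every distinct score as a threshold; `TPR = TP / (TP + FN)` versus
#' `FPR = FP / (FP + TN)`. Tied scores step jointly, so the trapezoidal area
#' equals the Mann-Whitney statistic exactly: the probability that a random
#' positive outscores a random negative, ties counted half.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Labels in `{+1, -1}`. A `cv_predictions` table may be
#'   passed as `scores` alone.
#' @return List of class `perf_curve`: `kind = "ROC"`, `points`
#'   (`data.frame` of `fpr`, `tpr`, `threshold`, beginning at (0,0)), `area`.
#' @export
roc_curve <- function(scores, labels = NULL) {
  if (inherits(scores, "cv_predictions")) {
    labels <- scores$label; scores <- scores$score
  }
  check_scored_labels(scores, labels)
  tc <- threshold_counts(scores, labels)
  P <- sum(labels > 0); N <- sum(labels < 0)
  tpr <- c(0, tc$tp / P); fpr <- c(0, tc$fp / N)
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(kind = "ROC",
                 points = data.frame(fpr = fpr, tpr = tpr,
                                     threshold = c(Inf, tc$threshold)),
                 area = area),
            class = "perf_curve")
}

#' Precision-recall curve and AUPRC
#'
#' `Precision = TP / (TP + FP)`, `Recall = TPR`, at every distinct
#' threshold. The area is non-interpolated average precision: precision
#' summed over recall increments. Preferred over ROC under large negative
#' imbalance, since it directly assesses positive predictions.
#'
#' @inheritParams roc_curve
#' @return List of class `perf_curve`: `kind = "PR"`, `points`
#'   (`recall`, `precision`, `threshold`), `area`.
#' @export
pr_curve <- function(scores, labels = NULL) {
  if (inherits(scores, "cv_predictions")) {
    labels <- scores$label; scores <- scores$score
  }
  check_scored_labels(scores, labels, need_neg = FALSE)
  tc <- threshold_counts(scores, labels)
  P <- sum(labels > 0)
  recall <- tc$tp / P
  precision <- tc$tp / (tc$tp + tc$fp)
  area <- sum(diff(c(0, recall)) * precision)   # average precision
  structure(list(kind = "PR",
                 points = data.frame(recall = recall, precision = precision,
                                     threshold = tc$threshold),
                 area = area),
            class = "perf_curve")
}

#' @export
print.perf_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d points, area = %.4f\n", x$kind,
              nrow(x$points), x$area))
  invisible(x)
}

#' Base-graphics plot of a performance curve
#' @param x A `perf_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.perf_curve <- function(x, ...) {
  if (x$kind == "ROC") {
    plot(x$points$fpr, x$points$tpr, type = "l", xlab = "FPR", ylab = "TPR",
         main = sprintf("ROC (AUROC = %.3f)", x$area), ...)
    graphics::abline(0, 1, lty = 2, col = "grey")
  } else {
    plot(x$points$recall, x$points$precision, type = "l", xlab = "Recall",
         ylab = "Precision", ylim = c(0, 1),
         main = sprintf("PR (AUPRC = %.3f)", x$area), ...)
  }
  invisible(x)
}
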