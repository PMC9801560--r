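# Imbalance-aware evaluation: Sn, Sp, G-mean, ROC / auROC, and
# normal-approximation confidence intervals over replicate runs.

#' Confusion counts from scores and labels
#'
#' @param scores Real-valued decision scores (predicted positive when
#'   `score > threshold`).
#' @param labels Labels in \{-1, +1\}.
#' @param threshold Decision threshold (default 0).
#' @return List with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0) {
  y <- .check_labels(labels, length(scores))
  pred <- ifelse(scores > threshold, 1, -1)
  list(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == -1),
       TN = sum(pred == -1 & y == -1), FN = sum(pred == -1 & y == 1))
}

#' Geometric mean of sensitivity and specificity
#'
#' `G-mean = sqrt(Sn * Sp)` with `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`; an
#' imbalance-robust summary of a thresholded classifier.
#'
#' @param counts A list with fields `TP`, `FP`, `TN`, `FN` (e.g. from
#'   [confusion_counts()]).
#' @return Value in \[0, 1\].
#' @examples
#' gmean(list(TP = 8, FN = 2, TN = 6, FP = 4))  # sqrt(0.8 * 0.6)
#' @export
gmean <- function(counts) {
  with(counts, {
    if (any(c(TP, FP, TN, FN) < 0)) stop("confusion counts must be nonnegative")
    if (TP + FN == 0 || TN + FP == 0) {
      stop("G-mean undefined: one class has no instances")
    }
    sqrt((TP / (TP + FN)) * (TN / (TN + FP)))
  })
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the distinct score values (tied
#' scores grouped into a single step, giving diagonal segments), tracing
#' `(FP_rate, TP_rate)` from (0, 0) to (1, 1); the area is computed by the
#' trapezoidal rule and equals the Mann-Whitney pairwise statistic (wins
#' plus half-ties over all positive-negative pairs).
#'
#' @param scores Finite real scores, higher = more positive.
#' @param labels Labels in \{-1, +1\}, both classes present.
#' @return An object of class `roc_result`: list with `points` (data frame
#'   `fpr`, `tpr`) and `auroc`.
#' @examples
#' roc_auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, -1, -1))$auroc  # 1
#' @export
roc_auroc <- function(scores, labels) {
  y <- .check_labels(labels, length(scores))
  if (any(!is.finite(scores))) stop("scores must be finite")
  npos <- sum(y == 1); nneg <- sum(y == -1)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys == 1); fp <- cumsum(ys == -1)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auroc = auroc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, auROC = %.4f\n", nrow(x$points), x$auroc))
  invisible(x)
}

#' Mean and 95% confidence halfwidth over replicates
#'
#' Normal-approximation interval `mean +/- 1.96 sd / sqrt(n)` over
#' independent replicate values of a metric.
#'
#' @param values Numeric vector of replicate values (length >= 2).
#' @return List with `mean` and `halfwidth`.
#' @export
ci95 <- function(values) {
  if (length(values) < 2) stop("at least 2 replicates required")
  list(mean = mean(values),
       halfwidth = 1.96 * stats::sd(values) / sqrt(length(values)))
}
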