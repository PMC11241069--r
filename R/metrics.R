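# Evaluation: accuracy, balanced accuracy, F1, ROC/AUC (threshold sweep +
# trapezoid), calibration curve.

#' ROC curve by threshold sweep
#'
#' Thresholds are the unique scores plus sentinels; tied scores collapse
#' onto one ROC point, so ties contribute half-concordance to the
#' trapezoidal AUC.
#'
#' @param y_true labels in {0, 1}
#' @param p1 class-1 scores/probabilities
#' @return data.frame with threshold, fpr, tpr
#' @export
rocCurve <- function(y_true, p1) {
  stopifnot(length(y_true) == length(p1))
  pos <- sum(y_true == 1L)
  neg <- sum(y_true == 0L)
  th <- c(Inf, sort(unique(p1), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) sum(p1 >= t & y_true == 1L) / pos,
                numeric(1L))
  fpr <- vapply(th, function(t) sum(p1 >= t & y_true == 0L) / neg,
                numeric(1L))
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1L) + tail(tpr[o], -1L)) / 2)
}

#' Compute the evaluation report
#'
#' Accuracy at the 0.5 threshold, balanced accuracy (mean per-class recall),
#' F1 of class 1, ROC point list, trapezoidal AUC, and a 10-bin calibration
#' curve. With a single-class truth vector the AUC is undefined and reported
#' as NA.
#'
#' @param y_true labels in {0, 1}
#' @param probs n x 2 probability matrix or a class-1 probability vector
#' @param bins calibration bins (default 10)
#' @return an \code{EvalReport} list
#' @export
computeMetrics <- function(y_true, probs, bins = 10L) {
  p1 <- if (is.matrix(probs)) probs[, 2L] else probs
  stopifnot(length(y_true) == length(p1))
  y_true <- as.integer(y_true)
  pred <- as.integer(p1 >= 0.5)
  acc <- mean(pred == y_true)
  recalls <- vapply(c(0L, 1L), function(c) {
    nc <- sum(y_true == c)
    if (nc == 0L) NA_real_ else sum(pred == c & y_true == c) / nc
  }, numeric(1L))
  bal_acc <- mean(recalls, na.rm = TRUE)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  if (length(unique(y_true)) < 2L) {
    roc <- NULL
    auc <- NA_real_
  } else {
    roc <- rocCurve(y_true, p1)
    auc <- trapezoid_auc(roc$fpr, roc$tpr)
  }
  structure(list(accuracy = acc, balanced_accuracy = bal_acc, f1 = f1,
                 roc = roc, auc = auc,
                 calibration = calibrationCurve(y_true, p1, bins = bins),
                 n = length(y_true)),
            class = "EvalReport")
}

#' Calibration curve (reliability diagram data)
#'
#' Equal-width bins on [0, 1]; per bin the mean predicted probability, the
#' observed class-1 frequency, and the count. Empty bins are omitted.
#'
#' @param y_true labels in {0, 1}
#' @param p1 class-1 probabilities in [0, 1]
#' @param bins number of bins (default 10)
#' @return data.frame with bin, mean_predicted, observed_frequency, count
#' @export
calibrationCurve <- function(y_true, p1, bins = 10L) {
  stopifnot(all(p1 >= 0 & p1 <= 1))
  idx <- pmin(floor(p1 * bins) + 1L, bins)
  keep <- sort(unique(idx))
  data.frame(
    bin = keep,
    mean_predicted = vapply(keep, function(b) mean(p1[idx == b]),
                            numeric(1L)),
    observed_frequency = vapply(keep, function(b) mean(y_true[idx == b]),
                                numeric(1L)),
    count = vapply(keep, function(b) sum(idx == b), integer(1L)))
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(
    "EvalReport (n=%d): accuracy %.3f, balanced accuracy %.3f, F1 %.3f, AUC %s\n",
    x$n, x$accuracy, x$balanced_accuracy, x$f1,
    if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}
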