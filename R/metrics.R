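#' Confusion counts at a probability threshold
#'
#' A sample is predicted positive (acquired resistance) iff its probability is
#' at or above `threshold`.
#'
#' @param y binary labels (AR = positive).
#' @param p predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return named list `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_at_threshold <- function(y, p, threshold = 0.5) {
  y <- label_to_binary(y)
  if (length(y) != length(p)) stop("y and p lengths differ")
  pred <- as.integer(p >= threshold)
  list(TP = sum(pred == 1 & y == 1), TN = sum(pred == 0 & y == 0),
       FP = sum(pred == 1 & y == 0), FN = sum(pred == 0 & y == 1))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive sample is
#' ranked above a random negative one, with ties counted one half — identical
#' to the trapezoidal area under the threshold-swept ROC curve.
#'
#' @param y binary labels; both classes must be present.
#' @param p scores or probabilities (any monotone transform gives the same
#'   AUROC).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y, p) {
  y <- label_to_binary(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Threshold sweep over the unique scores: one (FPR, TPR) point per threshold,
#' anchored at (0,0) and (1,1), plus the trapezoidal area.
#'
#' @inheritParams auroc
#' @return data.frame `threshold`, `fpr`, `tpr` with attribute `"area"`.
#' @export
roc_curve <- function(y, p) {
  y <- label_to_binary(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  th <- c(Inf, sort(unique(p), decreasing = TRUE), -Inf)
  pts <- t(vapply(th, function(t) {
    pred <- p >= t
    c(fpr = sum(pred & y == 0) / n0, tpr = sum(pred & y == 1) / n1)
  }, c(fpr = 0, tpr = 0)))
  out <- data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  area <- sum(diff(out$fpr) * (head(out$tpr, -1) + tail(out$tpr, -1)) / 2)
  attr(out, "area") <- area
  out
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean. An
#' undefined ratio (zero denominator) is reported as 0 with a warning, so
#' reports stay numeric.
#'
#' @param cc confusion counts from [confusion_at_threshold()].
#' @return named list `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cc) {
  precision <- if (cc$TP + cc$FP == 0) {
    warning("no predicted positives: precision reported as 0", call. = FALSE)
    0
  } else cc$TP / (cc$TP + cc$FP)
  recall <- if (cc$TP + cc$FN == 0) {
    warning("no true positives in data: recall reported as 0", call. = FALSE)
    0
  } else cc$TP / (cc$TP + cc$FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * recall * precision / (recall + precision)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Brier score
#'
#' Mean squared error between predicted probabilities and the 0/1 outcome;
#' lower is better, 0 for a perfect confident prediction.
#'
#' @inheritParams auroc
#' @return non-negative scalar.
#' @export
brier <- function(y, p) {
  y <- label_to_binary(y)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  mean((p - y)^2)
}

#' Matthews correlation coefficient
#'
#' `((TP*TN) - (FP*FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, ranging from
#' -1 (total inversion) to 1 (perfect). If any factor under the root is zero
#' (e.g. all predictions in one class) the score is 0 by convention.
#'
#' @param cc confusion counts.
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(cc) {
  denom <- as.numeric(cc$TP + cc$FP) * (cc$TP + cc$FN) *
    (cc$TN + cc$FP) * (cc$TN + cc$FN)
  if (denom == 0) return(0)
  ((as.numeric(cc$TP) * cc$TN) - (as.numeric(cc$FP) * cc$FN)) / sqrt(denom)
}

#' Full metric report
#'
#' AUROC plus the thresholded metrics (accuracy, precision, recall, F1, MCC)
#' and the Brier score.
#'
#' @inheritParams confusion_at_threshold
#' @return named list of metrics and the threshold used.
#' @export
evaluate_all <- function(y, p, threshold = 0.5) {
  cc <- confusion_at_threshold(y, p, threshold)
  prf <- precision_recall_f1(cc)
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  list(auroc = auroc(y, p),
       accuracy = (cc$TP + cc$TN) / n,
       precision = prf$precision, recall = prf$recall, f1 = prf$f1,
       brier = brier(y, p),
       mcc = mcc(cc),
       threshold = threshold,
       confusion = cc)
}
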