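# Evaluation metrics for the binary task (malignant = positive class):
# confusion counts, precision/recall/F-measure, precision-recall curve and
# average precision (all-points precision envelope), mean AP, and ROC/AUC
# (trapezoidal over distinct thresholds, equivalent to the normalized
# Mann-Whitney U statistic with ties rank-averaged).

#' Binary confusion counts
#'
#' @param labels true 0/1 labels (1 = malignant = positive).
#' @param predictions predicted 0/1 labels.
#' @return named integer vector `TP`, `FP`, `FN`, `TN`.
#' @export
confusionCounts <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions))
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  c(TP = sum(labels == 1L & predictions == 1L),
    FP = sum(labels == 0L & predictions == 1L),
    FN = sum(labels == 1L & predictions == 0L),
    TN = sum(labels == 0L & predictions == 0L))
}

#' Precision, recall and weighted F-measure
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F_alpha = (alpha^2+1) P R / (alpha^2 P + R)` (harmonic mean at
#' `alpha = 1`).  When a denominator is zero the corresponding metric is 0
#' and the result carries a `degenerate` attribute naming it.
#'
#' @param counts output of [confusionCounts()].
#' @param alpha recall weight (default 1).
#' @return named numeric vector `precision`, `recall`, `f`.
#' @export
prf <- function(counts, alpha = 1) {
  degenerate <- character()
  TP <- counts["TP"]; FP <- counts["FP"]; FN <- counts["FN"]
  if (TP + FP > 0) P <- TP / (TP + FP) else { P <- 0; degenerate <- c(degenerate, "precision") }
  if (TP + FN > 0) R <- TP / (TP + FN) else { R <- 0; degenerate <- c(degenerate, "recall") }
  if (alpha^2 * P + R > 0) f <- (alpha^2 + 1) * P * R / (alpha^2 * P + R)
  else { f <- 0; degenerate <- c(degenerate, "f") }
  out <- c(precision = unname(P), recall = unname(R), f = unname(f))
  attr(out, "degenerate") <- degenerate
  out
}

#' Precision-recall curve and average precision
#'
#' Sweeps every distinct score threshold (all-points curve) and integrates
#' the precision envelope (at each recall, the maximum precision achieved at
#' that recall or higher) over recall — the continuous-AP convention.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels true 0/1 labels; both classes must be present.
#' @return list with `curve` (data.frame `threshold`, `recall`, `precision`)
#'   and `ap`.
#' @export
prCurveAP <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("average precision is undefined for single-class labels")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # keep the last point of each tied-score block
  last <- c(diff(s) != 0, TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  P <- sum(labels)
  rec <- tp / P
  prec <- tp / (tp + fp)
  # precision envelope: running max from high recall back to low
  env <- rev(cummax(rev(prec)))
  ap <- sum(diff(c(0, rec)) * env)
  list(curve = data.frame(threshold = thr, recall = rec, precision = prec),
       ap = ap)
}

#' Mean average precision
#'
#' @param per_class_aps numeric vector of per-class APs.
#' @return their arithmetic mean.
#' @export
meanAP <- function(per_class_aps) mean(per_class_aps)

#' ROC curve and AUC
#'
#' Trapezoidal area under the ROC curve built over distinct score
#' thresholds.  Tied scores contribute a diagonal segment, so the AUC equals
#' the Mann-Whitney U statistic (rank-averaged ties) normalized by
#' `n_pos * n_neg`.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels true 0/1 labels; both classes must be present.
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0 || N == 0) stop("ROC is undefined for single-class labels")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(diff(s) != 0, TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Full evaluation report from scores
#'
#' Thresholds scores at 0 for the confusion-based metrics and adds AP and
#' AUC from the score ranking.
#'
#' @param scores signed decision scores (positive = predicted malignant).
#' @param labels true 0/1 labels.
#' @param alpha F-measure weight.
#' @return named list: `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `f1`, `auc`, `ap`.
#' @export
evalReport <- function(scores, labels, alpha = 1) {
  cm <- confusionCounts(labels, as.integer(scores > 0))
  pr <- prf(cm, alpha)
  list(sensitivity = unname(pr["recall"]),
       specificity = unname(if ((cm["TN"] + cm["FP"]) > 0)
         cm["TN"] / (cm["TN"] + cm["FP"]) else 0),
       precision = unname(pr["precision"]),
       accuracy = unname((cm["TP"] + cm["TN"]) / sum(cm)),
       f1 = unname(pr["f"]),
       auc = rocAuc(scores, labels)$auc,
       ap = prCurveAP(scores, labels)$ap)
}
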