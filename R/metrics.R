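#' @title Screening metrics
#' @description Sensitivity, specificity, accuracy, Cohen's kappa, F1 and
#'   ROC AUC from a binary confusion matrix with malignant as the positive
#'   class, plus reconstruction of integer confusion matrices from published
#'   sensitivity/specificity and class counts (so printed result tables can
#'   be audited for internal consistency).
#' @name metrics-eval
NULL

#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth character/factor vectors of
#'   `"benign"`/`"malignant"` labels.
#' @return A [ConfusionMatrix-class] (positive class = malignant).
#' @export
confusionFromLabels <- function(predicted, truth) {
  p <- .asLabel(predicted); t <- .asLabel(truth)
  stopifnot(length(p) == length(t), !anyNA(p), !anyNA(t))
  confusionCounts(TP = sum(p == "malignant" & t == "malignant"),
                  FN = sum(p == "benign" & t == "malignant"),
                  TN = sum(p == "benign" & t == "benign"),
                  FP = sum(p == "malignant" & t == "benign"))
}

#' Compute screening metrics from a confusion matrix
#'
#' Implements `Sen = TP/(TP+FN)`, `Spe = TN/(TN+FP)`,
#' `Acc = (TP+TN)/total`, Cohen's kappa `(Po - Pe)/(1 - Pe)` with
#' `Po = Acc` and
#' `Pe = ((TP+FN)(TP+FP) + (FP+TN)(FN+TN)) / total^2`, and F1. The primary
#' F1 is the precision/recall harmonic mean
#' (`Precision = TP/(TP+FP)`); `f1Definition = "sen-spe"` instead uses
#' `2*Sen*Spe/(Sen+Spe)`. Percentages are rounded half-up to 2 decimals for
#' reporting; metrics with a zero denominator are `NA` (undefined, not 0).
#'
#' @param cm a [ConfusionMatrix-class].
#' @param f1Definition `"precision-recall"` (default) or `"sen-spe"`.
#' @param auc optional AUC fraction to carry in the report.
#' @return A [MetricsReport-class] with percentage-scale metrics.
#' @examples
#' computeMetrics(confusionCounts(131, 1, 159, 23))
#' @export
computeMetrics <- function(cm, f1Definition = c("precision-recall", "sen-spe"),
                           auc = NA_real_) {
  f1Definition <- match.arg(f1Definition)
  TP <- cm@TP; FN <- cm@FN; TN <- cm@TN; FP <- cm@FP
  total <- TP + FN + TN + FP
  if (total == 0L) stop("empty confusion matrix")
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- sdiv(TP, TP + FN)
  spe <- sdiv(TN, TN + FP)
  po <- (TP + TN) / total
  pe <- ((TP + FN) * (TP + FP) + (FP + TN) * (FN + TN)) / total^2
  kappa <- if (pe >= 1) { if (po >= 1) 1 else NA_real_ } else (po - pe) / (1 - pe)
  f1 <- if (f1Definition == "precision-recall") {
    prec <- sdiv(TP, TP + FP)
    if (is.na(prec) || is.na(sen) || prec + sen == 0) NA_real_
    else 2 * prec * sen / (prec + sen)
  } else {
    if (is.na(sen) || is.na(spe) || sen + spe == 0) NA_real_
    else 2 * sen * spe / (sen + spe)
  }
  pct <- function(x) if (is.na(x)) NA_real_ else roundHalfUp(100 * x, 2)
  new("MetricsReport",
      sensitivity = pct(sen), specificity = pct(spe), accuracy = pct(po),
      kappa = pct(kappa), f1 = pct(f1), auc = auc, po = po, pe = pe, cm = cm)
}

#' Reconstruct an integer confusion matrix from printed rates
#'
#' Given the test-set class counts and a published sensitivity and
#' specificity (percent), recovers the unique integer confusion matrix they
#' round to: `TP = round(sen * nMalignant / 100)`,
#' `TN = round(spe * nBenign / 100)` (half-up), with the complements as FN
#' and FP. Together with [computeMetrics()] this audits whether a printed
#' accuracy/kappa/F1 row is self-consistent.
#'
#' @param nMalignant,nBenign positive class counts.
#' @param senPercent,spePercent printed rates on the 0-100 scale.
#' @return A [ConfusionMatrix-class].
#' @examples
#' reconstructConfusion(132, 182, 99.24, 87.36) # TP=131 FN=1 TN=159 FP=23
#' @export
reconstructConfusion <- function(nMalignant, nBenign, senPercent, spePercent) {
  stopifnot(nMalignant > 0, nBenign > 0,
            senPercent >= 0, senPercent <= 100,
            spePercent >= 0, spePercent <= 100)
  TP <- roundHalfUp(senPercent * nMalignant / 100)
  TN <- roundHalfUp(spePercent * nBenign / 100)
  confusionCounts(TP = TP, FN = nMalignant - TP, TN = TN, FP = nBenign - TN)
}

#' ROC AUC by the rank (trapezoidal) estimator
#'
#' Equivalent to the Mann-Whitney statistic: ties between scores are handled
#' by midranks, which matches the trapezoidal area under the empirical ROC
#' curve over all thresholds.
#'
#' @param scores numeric malignancy scores.
#' @param labels `"benign"`/`"malignant"` per score.
#' @return AUC as a fraction in `[0, 1]`.
#' @examples
#' rocAuc(c(0.1, 0.2, 0.8, 0.9), c("benign", "benign", "malignant", "malignant"))
#' @export
rocAuc <- function(scores, labels) {
  y <- .asLabel(labels)
  stopifnot(length(scores) == length(y), !anyNA(y))
  n1 <- sum(y == "malignant"); n0 <- sum(y == "benign")
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == "malignant"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
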