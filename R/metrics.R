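#' Confusion counts for binary PD classification
#'
#' The positive class is PD (label 1): `TP` counts PD samples predicted PD,
#' `TN` healthy predicted healthy.
#'
#' @param labels true binary labels (0 healthy, 1 PD).
#' @param predictions predicted binary labels.
#' @return an object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions),
            all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  structure(list(TP = sum(labels == 1 & predictions == 1),
                 TN = sum(labels == 0 & predictions == 0),
                 FP = sum(labels == 0 & predictions == 1),
                 FN = sum(labels == 1 & predictions == 0)),
            class = "confusion_counts")
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from the rank statistic with midranks
#' for ties; no curve interpolation.
#'
#' @param labels binary labels (1 = positive).
#' @param scores real-valued scores, larger = more positive.
#' @return AUC in `[0, 1]`; `NA` if either class is empty.
#' @export
auc_rank <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The ten performance measures from confusion counts
#'
#' Computes ACC, MCR, precision, recall (sensitivity), specificity, FPR,
#' FNR, F1 and MCC from the counts, and AUC from `scores`/`labels` via
#' [auc_rank()] when provided. A metric whose denominator is zero is
#' reported as `NA` and named in the `undefined` attribute; AUC without
#' scores is `NA`, never fabricated.
#'
#' @param cc a [confusion()] object.
#' @param scores optional real-valued scores for AUC.
#' @param labels labels matching `scores` (required with `scores`).
#' @return an object of class `metrics_report`.
#' @export
metrics_from_confusion <- function(cc, scores = NULL, labels = NULL) {
  stopifnot(inherits(cc, "confusion_counts"))
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  n <- TP + TN + FP + FN
  undefined <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  acc <- div(TP + TN, n, "ACC")
  precision <- div(TP, TP + FP, "precision")
  recall <- div(TP, TP + FN, "recall")
  specificity <- div(TN, TN + FP, "specificity")
  fpr <- div(FP, TN + FP, "FPR")
  fnr <- div(FN, TP + FN, "FNR")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undefined <- c(undefined, "F1"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "MCC"); NA_real_ }
         else (TP * TN - FP * FN) / mcc_den
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(labels)) stop("labels are required to compute AUC from scores")
    auc <- auc_rank(labels, scores)
  }
  structure(list(ACC = acc, MCR = if (is.na(acc)) NA_real_ else 1 - acc,
                 AUC = auc, precision = precision, recall = recall,
                 specificity = specificity, FPR = fpr, FNR = fnr,
                 F1 = f1, MCC = mcc, counts = cc),
            class = "metrics_report", undefined = undefined)
}

#' @export
print.metrics_report <- function(x, ...) {
  cc <- x$counts
  cat(sprintf("confusion (positive = PD): TP %d  TN %d  FP %d  FN %d\n",
              cc$TP, cc$TN, cc$FP, cc$FN))
  for (m in c("ACC", "MCR", "AUC", "precision", "recall", "specificity",
              "FPR", "FNR", "F1", "MCC"))
    cat(sprintf("  %-12s %s\n", m,
                ifelse(is.na(x[[m]]), "undefined", sprintf("%.4f", x[[m]]))))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(ACC = x$ACC, MCR = x$MCR, AUC = x$AUC, precision = x$precision,
             recall = x$recall, specificity = x$specificity, FPR = x$FPR,
             FNR = x$FNR, F1 = x$F1, MCC = x$MCC,
             TP = x$counts$TP, TN = x$counts$TN,
             FP = x$counts$FP, FN = x$counts$FN)
}

#' Evaluate a trained detector on a dataset
#'
#' Binary predictions feed the confusion counts; the PD unit's pre-threshold
#' activations provide the AUC scores.
#'
#' @param det a `trained_detector`.
#' @param ds a `spike_dataset`.
#' @return a `metrics_report`.
#' @export
evaluate <- function(det, ds) {
  pred <- predict(det, ds, "binary")
  scores <- predict(det, ds, "score")
  metrics_from_confusion(confusion(ds$label, pred), scores, ds$label)
}
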