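## Confusion-matrix metrics: ACC, Recall, Precision, MCC.

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN); Recall = TP/(TP+FN);
#' Precision = TP/(TP+FP);
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric with a zero denominator is reported as 0 and flagged in the
#' `undefined` field.
#'
#' @param TP,TN,FP,FN non-negative integer counts, sum > 0.
#' @return a `hydro_metrics` list: the four counts, `ACC`, `Recall`,
#'   `Precision`, `MCC`, `undefined` (character vector of flagged metrics).
#' @export
compute_metrics <- function(TP, TN, FP, FN) {
  ## double arithmetic: the MCC denominator overflows 32-bit integers
  ## already at a few hundred test atoms
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all confusion counts are zero")
  undefined <- character()
  acc <- (TP + TN) / (TP + TN + FP + FN)
  recall <- if (TP + FN > 0) TP / (TP + FN) else { undefined <- c(undefined, "Recall"); 0 }
  precision <- if (TP + FP > 0) TP / (TP + FP) else { undefined <- c(undefined, "Precision"); 0 }
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else {
    undefined <- c(undefined, "MCC"); 0
  }
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 ACC = acc, Recall = recall, Precision = precision,
                 MCC = mcc, undefined = undefined),
            class = "hydro_metrics")
}

#' @export
print.hydro_metrics <- function(x, ...) {
  cat(sprintf("TP %.0f  TN %.0f  FP %.0f  FN %.0f | ACC %.4f  Recall %.4f  Precision %.4f  MCC %.4f%s\n",
              x$TP, x$TN, x$FP, x$FN, x$ACC, x$Recall, x$Precision, x$MCC,
              if (length(x$undefined))
                paste0("  [undefined: ", paste(x$undefined, collapse = ","), "]")
              else ""))
  invisible(x)
}

## Metrics from prediction/label vectors at a threshold.
metrics_from_predictions <- function(prob, y, threshold = 0.5) {
  y <- as_binary_label(y)
  pred <- as.integer(prob >= threshold)
  compute_metrics(TP = sum(pred == 1L & y == 1L), TN = sum(pred == 0L & y == 0L),
                  FP = sum(pred == 1L & y == 0L), FN = sum(pred == 0L & y == 1L))
}
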