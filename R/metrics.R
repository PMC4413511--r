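#' Confusion counts from truth and predictions
#'
#' @param truth,pred Label vectors in {-1, +1}.
#' @return A list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  list(TP = sum(truth == 1L & pred == 1L),
       FP = sum(truth == -1L & pred == 1L),
       TN = sum(truth == -1L & pred == -1L),
       FN = sum(truth == 1L & pred == -1L))
}

#' Classification metrics from a confusion table
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Ac = (TP+TN)/total and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' Any zero factor in the MCC denominator yields MCC = 0 (the usual
#' convention for degenerate predictors); Sn/Sp are NA when their class is
#' absent.
#'
#' @param counts List or vector with `TP`, `FP`, `TN`, `FN` (non-negative).
#' @return A list with `Sn`, `Sp`, `Ac`, `MCC`.
#' @export
#' @examples
#' compute_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2))  # MCC = 10/sqrt(600)
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative counts")
  total <- tp + fp + tn + fn
  if (total == 0) stop("all-zero confusion counts")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fn * fp) / sqrt(denom) else 0
  list(Sn = sn, Sp = sp, Ac = (tp + tn) / total, MCC = mcc)
}
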