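#' Confusion matrix for binary predictions
#'
#' @param predicted,actual 0/1 vectors (1 = effective).
#' @return object of class `confusion_matrix`: list with integer counts
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(predicted, actual) {
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  stop_if_not(length(predicted) == length(actual) && length(actual) > 0,
              "prediction/label length mismatch or empty input")
  stop_if_not(all(c(predicted, actual) %in% c(0L, 1L)),
              "predictions and labels must be 0/1")
  structure(list(TP = sum(predicted == 1L & actual == 1L),
                 TN = sum(predicted == 0L & actual == 0L),
                 FP = sum(predicted == 1L & actual == 0L),
                 FN = sum(predicted == 0L & actual == 1L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, recall (sensitivity), specificity, precision,
#' F-measure (`2 * recall * precision / (recall + precision)`) and Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`.
#'
#' Degenerate denominators: a ratio whose denominator is zero because the
#' corresponding error count is zero is defined as 1 (e.g. specificity with
#' no negatives present and none predicted); the MCC is 0 when its
#' denominator vanishes.
#'
#' @param cm a [confusion_matrix()] (or list with `TP`, `TN`, `FP`, `FN`).
#' @return object of class `metrics_report`: the six metrics plus the
#'   counts.  Printing rounds to 4 decimals, half-up.
#' @export
compute_metrics <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  n <- TP + TN + FP + FN
  stop_if_not(n > 0, "empty confusion matrix")
  ratio <- function(num, den) if (den == 0) 1 else num / den
  accuracy <- (TP + TN) / n
  recall <- ratio(TP, TP + FN)
  specificity <- ratio(TN, TN + FP)
  precision <- ratio(TP, TP + FP)
  f_measure <- if (recall + precision == 0) 0
               else 2 * recall * precision / (recall + precision)
  mcc_den <- sqrt(TP + FP) * sqrt(TN + FN) * sqrt(TP + FN) * sqrt(TN + FP)
  mcc <- if (mcc_den == 0) 0
         else (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  structure(list(accuracy = accuracy, recall = recall,
                 specificity = specificity, precision = precision,
                 f_measure = f_measure, mcc = mcc,
                 confusion = list(TP = TP, TN = TN, FP = FP, FN = FN)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- round_half_up(unlist(x[c("accuracy", "recall", "specificity",
                                "precision", "f_measure", "mcc")]), 4)
  cat(sprintf(
    "Accuracy %.4f | Recall %.4f | Specificity %.4f | Precision %.4f | F %.4f | MCC %.4f\n",
    v[1], v[2], v[3], v[4], v[5], v[6]))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, recall = x$recall,
             specificity = x$specificity, precision = x$precision,
             f_measure = x$f_measure, mcc = x$mcc,
             TP = x$confusion$TP, TN = x$confusion$TN,
             FP = x$confusion$FP, FN = x$confusion$FN)
}

#' Recover integer confusion matrices from printed metrics
#'
#' Published tables often report accuracy, recall and precision rounded to
#' 4 decimals without the underlying counts.  This searches exhaustively
#' over nonnegative integer `(TP, FP, FN, TN)` with total in `n_range` and
#' returns every matrix whose accuracy, recall and precision round
#' (half-up, 4 decimals) to the given values — from which the remaining
#' metrics (F-measure, MCC) can be recomputed exactly.
#'
#' @param accuracy,recall,precision printed values (4-decimal rounding
#'   assumed).
#' @param n_range integer vector (its range is used) of plausible totals.
#' @return list of [confusion_matrix()] objects (possibly of length > 1 if
#'   the metrics are ambiguous at that precision).
#' @export
recover_confusion_from_metrics <- function(accuracy, recall, precision,
                                           n_range) {
  stop_if_not(all(c(accuracy, recall, precision) >= 0) &&
                all(c(accuracy, recall, precision) <= 1),
              "metrics must lie in [0, 1]")
  ns <- seq.int(min(n_range), max(n_range))
  matches <- list()
  eq4 <- function(x, target) round_half_up(x, 4) == round_half_up(target, 4)
  for (n in ns) {
    for (TP in 0:n) {
      ## recall fixes TP + FN given TP (within rounding); enumerate FN, FP
      for (FN in 0:(n - TP)) {
        pos <- TP + FN
        rec <- if (pos == 0) 1 else TP / pos
        if (!eq4(rec, recall)) next
        for (FP in 0:(n - TP - FN)) {
          prec <- if (TP + FP == 0) 1 else TP / (TP + FP)
          if (!eq4(prec, precision)) next
          TN <- n - TP - FN - FP
          if (!eq4((TP + TN) / n, accuracy)) next
          matches[[length(matches) + 1L]] <-
            confusion_matrix_counts(TP, TN, FP, FN)
        }
      }
    }
  }
  stop_if_not(length(matches) > 0,
              "no integer confusion matrix matches in the given range")
  matches
}

confusion_matrix_counts <- function(TP, TN, FP, FN) {
  structure(list(TP = as.integer(TP), TN = as.integer(TN),
                 FP = as.integer(FP), FN = as.integer(FN)),
            class = "confusion_matrix")
}
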