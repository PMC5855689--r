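#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique observed scores (samples with
#' score at or above the threshold are called effective), recording
#' sensitivity and 1 - specificity at each, and integrates the curve by the
#' trapezoidal rule.  The resulting AUC equals the Mann-Whitney concordant-
#' pair statistic with half credit for tied scores.
#'
#' @param scores numeric scores, higher = more likely effective.
#' @param labels 0/1 labels; both classes must be present.
#' @return object of class `roc_curve`: data frame `points` with columns
#'   `threshold`, `fpr` (1 - specificity), `tpr` (sensitivity), and the
#'   scalar `auc`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stop_if_not(length(scores) == length(labels), "length mismatch")
  stop_if_not(all(labels %in% c(0L, 1L)), "labels must be 0/1")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  stop_if_not(npos > 0 && nneg > 0, "both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l == 1L); cum_fp <- cumsum(l == 0L)
  last <- cumsum(tabulate(match(s, thr), length(thr)))  # last index per thr
  tpr <- c(0, cum_tp[last] / npos)
  fpr <- c(0, cum_fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = c(Inf, thr),
                                     fpr = fpr, tpr = tpr),
                 auc = auc, n_positive = npos, n_negative = nneg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f (%d pos / %d neg)\n",
              nrow(x$points) - 1L, x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", sprintf("AUC = %.4f", x$auc), bty = "n")
  invisible(x)
}

#' Export ROC points and AUC
#'
#' Writes `<prefix>.tsv` (threshold, fpr, tpr) and `<prefix>.json` (AUC and
#' class counts).
#'
#' @param roc a `roc_curve`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
export_roc <- function(roc, prefix) {
  stopifnot(inherits(roc, "roc_curve"))
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  utils::write.table(roc$points, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(auc = roc$auc, n_positive = roc$n_positive,
                            n_negative = roc$n_negative),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
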