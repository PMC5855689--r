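#' Rank-based inverse normal transformation
#'
#' Fits, per column, the monotone map value -> `qnorm((r - 3/8) / (n + 1/4))`
#' where `r` is the (average, for ties) rank of the value among the fitted
#' sample.  The transformed columns have approximately standard-normal
#' marginals regardless of the raw distribution, which is what the
#' correlation-whitened classifier assumes.  Constant columns carry no rank
#' information: they are flagged and mapped to 0.
#'
#' @param X numeric matrix over all samples available for fitting (labeled
#'   and unlabeled together, typically).
#' @return object of class `normal_transform`: per-column knot tables
#'   (`value`, `score`), the fitted sample size `n`, and `constant` flags.
#' @examples
#' t <- fit_normal_transform(cbind(a = c(5, 1, 3)))
#' predict(t, cbind(a = c(5, 1, 3)))  # 0.8046, -0.8046, 0
#' @export
fit_normal_transform <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  stop_if_not(n >= 3, "at least 3 samples are needed to fit the transform")
  maps <- vector("list", ncol(X))
  constant <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    u <- sort(unique(v))
    if (length(u) == 1L) {
      constant[j] <- TRUE
      maps[[j]] <- list(value = u, score = 0)
      next
    }
    r <- rank(v, ties.method = "average")
    s <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
    ## tied raw values share an average rank, hence a single score per value
    maps[[j]] <- list(value = u, score = s[match(u, v)])
  }
  if (any(constant)) {
    message(sprintf("%d constant column(s) flagged; mapped to 0",
                    sum(constant)))
  }
  structure(list(maps = maps, n = n, constant = constant,
                 colnames = colnames(X)),
            class = "normal_transform")
}

#' Apply a fitted normal transformation
#'
#' Fitted values map to their fitted scores exactly; values between two
#' fitted values are linearly interpolated; values beyond the fitted range
#' clip to the extreme fitted scores (new data cannot outrank the training
#' extremes).
#'
#' @param object a fitted `normal_transform`.
#' @param newdata numeric matrix with the same columns as the fitted data.
#' @param ... unused.
#' @return transformed numeric matrix.
#' @export
predict.normal_transform <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stop_if_not(ncol(newdata) == length(object$maps),
              "column count differs from the fitted data")
  out <- matrix(0, nrow(newdata), ncol(newdata),
                dimnames = dimnames(newdata))
  for (j in seq_len(ncol(newdata))) {
    m <- object$maps[[j]]
    if (object$constant[j]) next  # stays 0
    out[, j] <- stats::approx(m$value, m$score, xout = newdata[, j],
                              method = "linear", rule = 2, ties = "ordered")$y
  }
  out
}

#' @export
print.normal_transform <- function(x, ...) {
  cat(sprintf("Rank-based inverse normal transform: %d columns fitted on %d samples",
              length(x$maps), x$n))
  if (any(x$constant)) cat(sprintf(" (%d constant)", sum(x$constant)))
  cat("\n")
  invisible(x)
}
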