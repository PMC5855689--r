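## Plug-in mutual information between two discrete vectors (natural log).
discrete_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  idx <- pxy > 0
  sum(pxy[idx] * log(pxy[idx] / outer(px, py)[idx]))
}

#' Minimum-redundancy maximum-relevance feature selection (MID scheme)
#'
#' Greedy forward selection over discrete features: the first feature
#' maximizes mutual information (MI) with the label; each subsequent feature
#' maximizes `MI(feature; y) - mean MI(feature; selected)` (the
#' mutual-information-difference criterion).  Ties break toward the lower
#' feature index, making the ordering deterministic.  Provided as the
#' conventional comparison baseline for [select_by_ellipse()].
#'
#' @param X discrete feature matrix (any small integer coding).
#' @param y 0/1 labels.
#' @param m number of features to select.
#' @return integer vector of `m` feature indices in selection order, with
#'   attribute `relevance` (MI of every feature with the label).
#' @export
select_by_mrmr <- function(X, y, m = 30) {
  stop_if_not(m >= 1, "m must be at least 1")
  p <- ncol(X)
  stop_if_not(m <= p, "m exceeds the number of features")
  relevance <- vapply(seq_len(p), function(j) discrete_mi(X[, j], y),
                      numeric(1))
  selected <- integer(0)
  ## cache pairwise MI lazily: redundancy[j] accumulates MI with chosen set
  red_sum <- numeric(p)
  remaining <- seq_len(p)
  for (step in seq_len(m)) {
    score <- if (step == 1) relevance[remaining]
             else relevance[remaining] - red_sum[remaining] / (step - 1)
    best <- remaining[which.max(score)]  # which.max takes the first maximum
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) && step < m) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) discrete_mi(X[, j], X[, best]),
               numeric(1))
    }
  }
  attr(selected, "relevance") <- relevance
  selected
}
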