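#' Collapse pair-encoded features to presence/absence
#'
#' Feature screening treats every feature as Bernoulli: any nonzero encoded
#' value (1 or 2 for binary categories, 1..4 for dose-coded side effects)
#' becomes 1.
#'
#' @param X integer matrix with nonnegative entries.
#' @return 0/1 integer matrix of the same shape.
#' @export
binarize <- function(X) {
  X <- as.matrix(X)
  stop_if_not(all(X >= 0), "binarize expects nonnegative entries")
  out <- (X != 0) * 1L
  dimnames(out) <- dimnames(X)
  out
}

#' Per-feature class frequencies
#'
#' `p1` is the frequency of a 1 among the negative samples, `p2` the
#' frequency among all labeled samples (positives and negatives mixed).
#' A feature whose prevalence differs between classes shows `p2 != p1`.
#'
#' @param X01 binarized pair matrix ([binarize()]).
#' @param y 0/1 labels (one per row of `X01`).
#' @return list with numeric vectors `p1` and `p2`.
#' @export
class_frequencies <- function(X01, y) {
  stop_if_not(length(y) == nrow(X01), "one label per row required")
  stop_if_not(all(y %in% c(0L, 1L)), "labels must be 0/1")
  stop_if_not(any(y == 0L), "at least one negative sample is required")
  list(p1 = colMeans(X01[y == 0L, , drop = FALSE]),
       p2 = colMeans(X01))
}

#' Ellipse screening statistic
#'
#' Under the null of no class difference, the point `(p1, p2 - p1)` falls
#' inside the ellipse `(p1 - 0.5)^2 / 0.5^2 + (p2 - p1)^2 / a^2 = 1` for a
#' significance parameter `a`.  The statistic returned is the critical value
#' `a*`: the smallest `a` whose ellipse still contains the point, so the
#' point lies outside the ellipse for a given `a` exactly when `a* > a`.
#' Features are ranked by `a*` descending.
#'
#' @param p1 frequency of 1 in negative samples (vectorized).
#' @param delta `p2 - p1` (vectorized, recycled against `p1`).
#' @return `a*`, nonnegative; 0 when `delta == 0`; `Inf` when `p1` is 0 or 1
#'   and `delta != 0` (the ellipse has zero height there).
#' @examples
#' ellipse_statistic(0.5, 0.2)   # 0.2: on the a = 0.2 ellipse
#' ellipse_statistic(0.25, 0.1)  # 0.1154701
#' @export
ellipse_statistic <- function(p1, delta) {
  stop_if_not(all(p1 >= 0 & p1 <= 1), "p1 must lie in [0, 1]")
  rad <- 1 - (p1 - 0.5)^2 / 0.25
  rad[rad < 0] <- 0  # guard FP noise at the endpoints
  out <- ifelse(delta == 0, 0,
                ifelse(rad <= 0, Inf, abs(delta) / sqrt(rad)))
  as.numeric(out)
}

#' Ellipse-based feature selection
#'
#' Ranks features by the ellipse critical value [ellipse_statistic()]
#' computed from binarized class frequencies, and keeps the top `m`
#' (ties broken by ascending feature index).  Equivalent to picking the
#' significance level `a` at which exactly `m` points fall outside the
#' ellipse, up to ties.
#'
#' @param X01 binarized pair matrix.
#' @param y 0/1 labels.
#' @param m number of features to keep (default 30).
#' @return object of class `feature_screen`: list with `p1`, `p2`, `delta`,
#'   `a_star`, `rank` (rank of each feature), `selected` (ordered indices of
#'   the chosen features) and `m`.
#' @export
select_by_ellipse <- function(X01, y, m = 30) {
  stop_if_not(m >= 1, "m must be at least 1")
  stop_if_not(m <= ncol(X01), "m exceeds the number of features")
  fr <- class_frequencies(X01, y)
  delta <- fr$p2 - fr$p1
  a_star <- ellipse_statistic(fr$p1, delta)
  ord <- order(-a_star, seq_along(a_star))
  rk <- integer(length(a_star)); rk[ord] <- seq_along(ord)
  structure(list(p1 = fr$p1, p2 = fr$p2, delta = delta, a_star = a_star,
                 rank = rk, selected = ord[seq_len(m)], m = as.integer(m),
                 feature_names = colnames(X01)),
            class = "feature_screen")
}

#' @export
print.feature_screen <- function(x, ...) {
  cat(sprintf("Ellipse feature screen: %d features, top %d selected\n",
              length(x$a_star), x$m))
  cat("  a* of selected: ",
      paste(signif(x$a_star[utils::head(x$selected, 5)], 4), collapse = ", "),
      if (x$m > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
plot.feature_screen <- function(x, a = NULL, ...) {
  plot(x$p1, x$delta, xlab = "p1 (frequency in negatives)",
       ylab = "p2 - p1", pch = 20,
       col = ifelse(seq_along(x$p1) %in% x$selected, "red", "grey40"), ...)
  if (!is.null(a)) {
    t <- seq(0, 2 * pi, length.out = 400)
    graphics::lines(0.5 + 0.5 * cos(t), a * sin(t), lty = 2)
  }
  invisible(x)
}

#' Export a feature screen as TSV (and scatter data) plus JSON
#'
#' Writes `<prefix>.tsv` with one row per feature (id, p1, p2, delta, a*,
#' rank, selected flag) — the `p1` and `delta` columns double as the
#' scatter-diagram coordinates — and `<prefix>.json` with the selection
#' configuration.
#'
#' @param screen a `feature_screen`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
export_feature_screen <- function(screen, prefix) {
  stopifnot(inherits(screen, "feature_screen"))
  ids <- screen$feature_names
  if (is.null(ids)) ids <- paste0("f", seq_along(screen$a_star))
  df <- data.frame(feature = ids, p1 = screen$p1, p2 = screen$p2,
                   delta = screen$delta, a_star = screen$a_star,
                   rank = screen$rank,
                   selected = as.integer(seq_along(ids) %in% screen$selected))
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(m = screen$m,
                            selected = screen$selected,
                            selected_features = ids[screen$selected]),
                       json, auto_unbox = TRUE)
  invisible(c(tsv, json))
}

#' Permutation calibration of the ellipse null
#'
#' Estimates the null distribution of the screening statistic by permuting
#' labels: for each permutation the maximum (or full set of) per-feature
#' `a*` values is recorded.  Useful for choosing a significance level `a`
#' empirically; the selection itself is rank-based and does not require one.
#'
#' @param X01 binarized matrix.
#' @param y 0/1 labels.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `a_star_null` (n_perm x n_features matrix) and
#'   `max_a_star` (per-permutation maximum).
#' @export
calibrate_ellipse_null <- function(X01, y, n_perm = 100, seed = NULL) {
  with_seed(seed, {
    res <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      fr <- class_frequencies(X01, yp)
      ellipse_statistic(fr$p1, fr$p2 - fr$p1)
    }, numeric(ncol(X01)))
    res <- t(res)
    list(a_star_null = res, max_a_star = apply(res, 1, max))
  })
}
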