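## In-fold feature selection dispatcher: returns column indices.
select_features <- function(X, y, selector = c("ellipse", "mrmr", "none"),
                            n_features = 30) {
  selector <- match.arg(selector)
  if (selector == "none") return(seq_len(ncol(X)))
  m <- min(n_features, ncol(X))
  if (selector == "ellipse") select_by_ellipse(binarize(X), y, m)$selected
  else as.integer(select_by_mrmr(binarize(X), y, m))
}

#' Leave-one-out cross-validation with in-fold feature selection
#'
#' Each sample is scored by a model fitted on the remaining `n - 1` samples.
#' Feature selection (when requested) is refitted inside every fold so that
#' the held-out label never influences the chosen features.  A fold whose
#' training part loses one of the two classes is skipped with a warning.
#'
#' @param spec a [classifier_spec()].
#' @param X feature matrix (all labeled samples, full feature set).
#' @param y 0/1 labels.
#' @param unlabeled optional unlabeled pool (forwarded to `improved_nb`).
#' @param selector `"ellipse"`, `"mrmr"` or `"none"` — feature screening run
#'   on the binarized training fold.
#' @param n_features number of features kept by the selector.
#' @return list with out-of-fold `scores` and hard `labels`, the true `y`,
#'   `metrics` (a [compute_metrics()] report), `roc` (a [roc_auc()] curve)
#'   and the indices of any `skipped` folds.
#' @export
loocv <- function(spec, X, y, unlabeled = NULL,
                  selector = c("ellipse", "mrmr", "none"), n_features = 30) {
  selector <- match.arg(selector)
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  stop_if_not(n >= 3, "LOOCV needs at least 3 samples")
  scores <- rep(NA_real_, n); labels <- rep(NA_integer_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    pr <- tryCatch({
      keep <- if (length(unique(ytr)) < 2L) seq_len(ncol(X))
              else select_features(X[-i, , drop = FALSE], ytr, selector,
                                   n_features)
      fit <- train_baseline(spec, X[-i, keep, drop = FALSE], ytr,
                            unlabeled = if (is.null(unlabeled)) NULL
                                        else unlabeled[, keep, drop = FALSE])
      predict_classifier(fit, X[i, keep, drop = FALSE])
    }, error = function(e) NULL)
    if (is.null(pr)) {
      skipped <- c(skipped, i)
      next
    }
    scores[i] <- pr$score; labels[i] <- pr$label
  }
  if (length(skipped)) {
    warning(sprintf("%d fold(s) skipped (training part unusable, e.g. a class vanished)",
                    length(skipped)))
  }
  ok <- !is.na(scores)
  list(scores = scores, labels = labels, y = y,
       metrics = compute_metrics(confusion_matrix(labels[ok], y[ok])),
       roc = roc_auc(scores[ok], y[ok]),
       skipped = skipped)
}

#' Random train/test split
#'
#' Uniform split without stratification; the training side gets
#' `floor(n * train_fraction)` samples.
#'
#' @param n number of samples (or an object with rows).
#' @param train_fraction fraction assigned to training (default 0.75).
#' @param seed integer seed for reproducibility.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, train_fraction = 0.75, seed = NULL) {
  if (!is.numeric(n) || length(n) > 1) n <- nrow(as.matrix(n))
  stop_if_not(train_fraction > 0 && train_fraction < 1,
              "train_fraction must lie strictly between 0 and 1")
  n_train <- floor(n * train_fraction)
  stop_if_not(n_train >= 1 && n_train < n,
              "both sides of the split must be nonempty")
  with_seed(seed, {
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Sweep positive-to-negative sampling ratios
#'
#' For each requested ratio `1:r`, samples `r` negatives per positive pair
#' with the chosen strategy, builds the encoded dataset, makes a 75/25
#' train/test split, selects features and trains on the training part, and
#' reports independent-test metrics and ROC.
#'
#' @param table a [drug_feature_table()].
#' @param positives positive pairs.
#' @param spec a [classifier_spec()].
#' @param strategy negative-sampling strategy, `"N1"` or `"N2"`.
#' @param universe drug universe for `"N2"`.
#' @param ratios integer negative multiples (default `c(1, 2, 3)` for
#'   1:1, 1:2, 1:3).
#' @param selector,n_features forwarded to [select_features()].
#' @param train_fraction forwarded to [split_train_test()].
#' @param unlabeled optional unlabeled pool matrix (full feature set).
#' @param seed integer seed; each ratio uses a derived sub-seed.
#' @return named list (one element per ratio) of lists with `metrics`,
#'   `roc`, `n_train`, `n_test`.
#' @export
ratio_sweep <- function(table, positives, spec, strategy = "N1",
                        universe = NULL, ratios = c(1, 2, 3),
                        selector = "ellipse", n_features = 30,
                        train_fraction = 0.75, unlabeled = NULL,
                        seed = NULL) {
  pos <- as_drug_pairs(positives)
  out <- list()
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    sub_seed <- if (is.null(seed)) NULL else seed + i
    neg <- generate_negative_pairs(strategy, pos, universe = universe,
                                   n = r * nrow(pos), seed = sub_seed)
    ds <- build_pair_dataset(table, pos, neg)
    sp <- split_train_test(nrow(ds$X), train_fraction, seed = sub_seed)
    Xtr <- ds$X[sp$train, , drop = FALSE]; ytr <- ds$y[sp$train]
    Xte <- ds$X[sp$test, , drop = FALSE]; yte <- ds$y[sp$test]
    keep <- select_features(Xtr, ytr, selector, n_features)
    fit <- train_baseline(spec, Xtr[, keep, drop = FALSE], ytr,
                          unlabeled = if (is.null(unlabeled)) NULL
                                      else unlabeled[, keep, drop = FALSE])
    pr <- predict_classifier(fit, Xte[, keep, drop = FALSE])
    out[[paste0("1:", r)]] <-
      list(metrics = compute_metrics(confusion_matrix(pr$label, yte)),
           roc = roc_auc(pr$score, yte),
           n_train = length(sp$train), n_test = length(sp$test))
  }
  out
}

#' y-randomization validation
#'
#' Refits the whole pipeline (feature selection + classifier, via LOOCV)
#' after randomly permuting the labels, `n_shuffles` times.  A model with
#' real signal keeps a high original AUC while the shuffled AUCs collapse to
#' chance; matching performance would indicate the model memorizes noise.
#' Permutation preserves the class counts exactly.
#'
#' @param spec a [classifier_spec()].
#' @param X,y labeled data (full feature set).
#' @param unlabeled,selector,n_features forwarded to [loocv()].
#' @param n_shuffles number of label permutations (default 3).
#' @param seed integer seed.
#' @param permutations optional list of explicit permutation index vectors
#'   (length `n`), overriding random shuffling — e.g. the identity
#'   permutation as a self-check.
#' @return list with `original` (a [loocv()] result), `shuffled` (list of
#'   [loocv()] results), `original_auc`, `shuffled_auc` (vector).
#' @export
y_randomization <- function(spec, X, y, unlabeled = NULL,
                            selector = "ellipse", n_features = 30,
                            n_shuffles = 3, seed = NULL,
                            permutations = NULL) {
  stop_if_not(n_shuffles >= 1, "n_shuffles must be at least 1")
  y <- as.integer(y)
  original <- loocv(spec, X, y, unlabeled, selector, n_features)
  if (is.null(permutations)) {
    permutations <- with_seed(seed, {
      lapply(seq_len(n_shuffles), function(i) sample(length(y)))
    })
  }
  shuffled <- lapply(permutations, function(perm) {
    loocv(spec, X, y[perm], unlabeled, selector, n_features)
  })
  list(original = original, shuffled = shuffled,
       original_auc = original$roc$auc,
       shuffled_auc = vapply(shuffled, function(s) s$roc$auc, numeric(1)))
}

#' Export a metrics report (with optional ROC) as JSON + TSV
#'
#' @param report a [compute_metrics()] result.
#' @param prefix output path prefix.
#' @param roc optional [roc_auc()] curve exported alongside.
#' @return invisibly, the paths written.
#' @export
export_metrics <- function(report, prefix, roc = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  df <- as.data.frame(report)
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- c(as.list(df),
               if (!is.null(roc)) list(auc = roc$auc))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc)) export_roc(roc, paste0(prefix, "_roc"))
  invisible(c(tsv, json))
}
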