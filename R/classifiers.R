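#' Specify a classifier
#'
#' One interface covers the improved naive Bayes model and the three
#' conventional baselines, so the evaluation protocols (LOOCV, splits,
#' ratio sweeps, y-randomization) treat them interchangeably.
#'
#' Defaults follow the reference configuration of each algorithm:
#' * `improved_nb`: correlation eigenbasis on (default `correlation = TRUE`);
#' * `categorical_nb`: naive Bayes with categorical per-feature likelihoods
#'   and Laplace smoothing 0 (zero-count categories contribute `-Inf`
#'   log-likelihood; an all-`-Inf` tie is resolved by the prior);
#' * `knn`: Euclidean k-nearest neighbours with `k = 5` and minimum vote
#'   `l = 2` for a definite decision (doubt is assigned non-effective);
#' * `svm_rbf`: RBF-kernel SVM with cost `C = 10` and kernel width
#'   `gamma = 0.1`, decision-function value as score.
#'
#' @param algorithm one of `"improved_nb"`, `"categorical_nb"`, `"knn"`,
#'   `"svm_rbf"`.
#' @param ... hyperparameter overrides (see above).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("improved_nb", "categorical_nb",
                                          "knn", "svm_rbf"), ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    improved_nb = list(correlation = TRUE, priors = "empirical"),
    categorical_nb = list(laplace = 0),
    knn = list(k = 5, l = 2),
    svm_rbf = list(C = 10, gamma = 0.1))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  stop_if_not(length(unknown) == 0,
              sprintf("unknown hyperparameter(s) for %s: %s", algorithm,
                      paste(unknown, collapse = ", ")))
  defaults[names(override)] <- override
  structure(list(algorithm = algorithm, hyperparameters = defaults),
            class = "classifier_spec")
}

#' Read a classifier spec from a JSON or YAML config file
#'
#' The file must contain `algorithm` and optionally `hyperparameters`.
#'
#' @param path config file (`.json`, `.yaml` or `.yml`).
#' @return a [classifier_spec()].
#' @export
read_classifier_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    stop_if_not(requireNamespace("yaml", quietly = TRUE),
                "the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  do.call(classifier_spec,
          c(list(algorithm = cfg$algorithm),
            as.list(cfg$hyperparameters)))
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v) paste(format(v),
                                                          collapse = "/"),
                     character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("Classifier spec: %s (%s)\n", x$algorithm, hp))
  invisible(x)
}

#' Train a classifier
#'
#' Fits the algorithm named by the spec on labeled pair vectors.  Every
#' fitted classifier yields, through [predict_classifier()], a per-sample
#' score for the effective class and a hard 0/1 label.
#'
#' @param spec a [classifier_spec()].
#' @param X feature matrix (selected, sum-encoded pair features).
#' @param y 0/1 labels.
#' @param unlabeled optional unlabeled pool (used by `improved_nb` only).
#' @return object of class `classifier_fit`.
#' @export
train_baseline <- function(spec, X, y, unlabeled = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  stop_if_not(all(y %in% c(0L, 1L)), "labels must be binary 0/1")
  hp <- spec$hyperparameters
  model <- switch(spec$algorithm,
    improved_nb = improved_nb(X, y, unlabeled = unlabeled,
                              priors = hp$priors,
                              correlation = hp$correlation),
    categorical_nb = fit_categorical_nb(X, y, laplace = hp$laplace),
    knn = list(X = X, y = y, k = hp$k, l = hp$l),
    svm_rbf = e1071::svm(x = X, y = factor(y, levels = c("0", "1")),
                         kernel = "radial", cost = hp$C, gamma = hp$gamma,
                         scale = FALSE))
  structure(list(spec = spec, model = model, n_features = ncol(X)),
            class = "classifier_fit")
}

#' @export
print.classifier_fit <- function(x, ...) {
  cat(sprintf("Fitted %s classifier on %d features\n",
              x$spec$algorithm, x$n_features))
  invisible(x)
}

#' Score and label new samples with a fitted classifier
#'
#' @param fit a [train_baseline()] result.
#' @param newdata feature matrix.
#' @return data frame with `score` (higher = more likely effective) and
#'   `label` (0/1).
#' @export
predict_classifier <- function(fit, newdata) {
  stopifnot(inherits(fit, "classifier_fit"))
  newdata <- as.matrix(newdata)
  stop_if_not(ncol(newdata) == fit$n_features, "feature count mismatch")
  out <- switch(fit$spec$algorithm,
    improved_nb = {
      s <- predict(fit$model, newdata, type = "score")
      data.frame(score = s, label = as.integer(s > 0))
    },
    categorical_nb = predict_categorical_nb(fit$model, newdata),
    knn = predict_knn_votes(fit$model, newdata),
    svm_rbf = {
      pr <- stats::predict(fit$model, newdata, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- as.numeric(dv[, 1])
      ## e1071 orients the decision value toward the first factor level
      if (!startsWith(colnames(dv)[1], "1")) s <- -s
      data.frame(score = s, label = as.integer(as.character(pr) == "1"))
    })
  rownames(out) <- NULL
  out
}

## ---- categorical naive Bayes (Laplace-configurable, exact zero handling) --

fit_categorical_nb <- function(X, y, laplace = 0) {
  levs <- lapply(seq_len(ncol(X)), function(j) sort(unique(X[, j])))
  counts <- lapply(c(0L, 1L), function(k) {
    Xk <- X[y == k, , drop = FALSE]
    lapply(seq_len(ncol(X)), function(j) {
      tab <- table(factor(Xk[, j], levels = levs[[j]]))
      as.numeric(tab)
    })
  })
  names(counts) <- c("0", "1")
  n_class <- c("0" = sum(y == 0L), "1" = sum(y == 1L))
  list(levels = levs, counts = counts, n_class = n_class,
       priors = n_class / sum(n_class), laplace = laplace)
}

predict_categorical_nb <- function(model, newdata) {
  n <- nrow(newdata); p <- ncol(newdata)
  loglik <- matrix(0, n, 2, dimnames = list(NULL, c("0", "1")))
  for (k in c("0", "1")) {
    for (j in seq_len(p)) {
      lev <- model$levels[[j]]
      cnt <- model$counts[[k]][[j]]
      num <- cnt + model$laplace
      den <- model$n_class[[k]] + model$laplace * length(lev)
      pj <- num / den
      idx <- match(newdata[, j], lev)   # unseen level -> NA -> zero count
      pv <- ifelse(is.na(idx), model$laplace / den, pj[idx])
      loglik[, k] <- loglik[, k] + ifelse(pv > 0, log(pv), -Inf)
    }
  }
  logpost <- sweep(loglik, 2, log(model$priors), "+")
  score <- logpost[, "1"] - logpost[, "0"]
  ## both classes impossible under the training counts: fall back to priors
  dead <- !is.finite(logpost[, "1"]) & !is.finite(logpost[, "0"])
  score[dead] <- 0
  label <- ifelse(dead,
                  as.integer(model$priors[["1"]] > model$priors[["0"]]),
                  as.integer(score > 0))
  data.frame(score = score, label = label)
}

## ---- k-nearest neighbours with a minimum-vote rule ------------------------

predict_knn_votes <- function(model, newdata) {
  cl <- factor(model$y, levels = c("0", "1"))
  ## definite decision requires the winner to reach l votes; class::knn
  ## returns NA ("doubt") otherwise, which we assign to non-effective
  hard <- class::knn(model$X, newdata, cl, k = model$k, l = model$l,
                     use.all = TRUE)
  soft <- class::knn(model$X, newdata, cl, k = model$k, l = 0, prob = TRUE,
                     use.all = TRUE)
  win_frac <- attr(soft, "prob")
  score <- ifelse(soft == "1", win_frac, 1 - win_frac)
  label <- as.integer(!is.na(hard) & hard == "1")
  data.frame(score = score, label = label)
}
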