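#' Improved naive Bayes: a correlation-whitened Gaussian discriminant
#'
#' Fits the semi-supervised classifier for effective-combination prediction.
#' The conditional-independence assumption of naive Bayes is relaxed by
#' working in the eigenbasis of the feature correlation matrix:
#'
#' 1. every feature is mapped to a standard-normal score by a rank-based
#'    inverse normal transform fitted on *all* samples (labeled plus any
#'    unlabeled candidate pool — label-free structure is legitimate prior
#'    knowledge);
#' 2. the correlation matrix `R` of the transformed features, again over all
#'    samples, is eigendecomposed into eigenvalues `lambda` and eigenvector
#'    matrix `P`;
#' 3. per-class means/SDs and overall means/SDs of the transformed features
#'    are estimated.
#'
#' Scoring projects the standardized sample onto `P`:
#' `beta = ((x - mu) / sigma) P` (overall standardization) and
#' `gamma_k = ((x - mu_k) / sigma_k) P` (class-k standardization), giving the
#' class-conditional score
#' `H_k = ln P(C_k) - sum_i (gamma_ki^2 / (2 lambda_i) + ln sigma_ki)`
#' (argmax is the predicted class when priors are meaningful) and the
#' prior-free membership score `L = sum_i (beta_i^2 - gamma_ki^2) / lambda_i`,
#' thresholded via a ROC curve (see [predict_by_threshold()]).
#'
#' @param X numeric/integer matrix of labeled samples (rows) by features;
#'   typically sum-encoded pair vectors restricted to the selected features.
#' @param y labels: 1 = effective, 0 = non-effective.
#' @param unlabeled optional matrix of unlabeled samples (same columns) used
#'   only for the normal transform, the correlation matrix and the overall
#'   moments.
#' @param priors `"empirical"` (class frequencies of `y`), a numeric vector
#'   of two probabilities named `"0"` and `"1"` (or in that order), or `NA`
#'   when no meaningful prior exists — then only threshold-based prediction
#'   via the `L` score is available.
#' @param correlation if `FALSE` the correlation matrix is forced to the
#'   identity, which reduces the model exactly to a Gaussian naive Bayes on
#'   the transformed features (useful for ablation).
#' @param lambda_floor,sigma_floor regularization floors: eigenvalues below
#'   `lambda_floor * n_features` are raised to it (then rescaled so that the
#'   eigenvalue sum equals the feature count), and standard deviations are
#'   floored at `sigma_floor`, since the scores divide by both.
#' @return an object of class `improved_nb`.
#' @seealso [predict.improved_nb()], [predict_by_threshold()],
#'   [write_improved_nb()]
#' @export
improved_nb <- function(X, y, unlabeled = NULL, priors = "empirical",
                        correlation = TRUE,
                        lambda_floor = 1e-6, sigma_floor = 1e-6) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stop_if_not(length(y) == nrow(X), "one label per row required")
  stop_if_not(all(y %in% c(0L, 1L)), "labels must be 0/1")
  stop_if_not(nrow(X) > 0, "empty input")
  cnt <- table(factor(y, levels = c(0L, 1L)))
  stop_if_not(all(cnt >= 2L), "each class needs at least 2 samples")
  if (!is.null(unlabeled)) {
    unlabeled <- as.matrix(unlabeled)
    stop_if_not(ncol(unlabeled) == ncol(X),
                "unlabeled pool must have the same features")
  }
  p <- ncol(X)
  all_X <- rbind(X, unlabeled)

  transform <- fit_normal_transform(all_X)
  Z_all <- predict(transform, all_X)
  Z_lab <- Z_all[seq_len(nrow(X)), , drop = FALSE]

  if (correlation) {
    R <- suppressWarnings(stats::cor(Z_all))
    R[is.na(R)] <- 0         # constant columns: no estimable correlation
    diag(R) <- 1
  } else {
    R <- diag(p)
  }
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, lambda_floor * p)
  lambda <- lambda * p / sum(lambda)
  P <- eig$vectors

  class_means <- rbind("0" = colMeans(Z_lab[y == 0L, , drop = FALSE]),
                       "1" = colMeans(Z_lab[y == 1L, , drop = FALSE]))
  class_sds <- rbind("0" = apply(Z_lab[y == 0L, , drop = FALSE], 2, stats::sd),
                     "1" = apply(Z_lab[y == 1L, , drop = FALSE], 2, stats::sd))
  class_sds <- pmax(class_sds, sigma_floor)
  overall_means <- colMeans(Z_all)
  overall_sds <- pmax(apply(Z_all, 2, stats::sd), sigma_floor)

  pr <- NULL
  if (identical(priors, "empirical")) {
    pr <- as.numeric(cnt) / sum(cnt)
    names(pr) <- c("0", "1")
  } else if (is.numeric(priors)) {
    stop_if_not(length(priors) == 2 && abs(sum(priors) - 1) < 1e-8,
                "priors must be two probabilities summing to 1")
    pr <- unname(priors)
    names(pr) <- if (!is.null(names(priors))) names(priors) else c("0", "1")
    pr <- pr[c("0", "1")]
  }

  structure(list(transform = transform, R = R, lambda = lambda, P = P,
                 class_means = class_means, class_sds = class_sds,
                 overall_means = overall_means, overall_sds = overall_sds,
                 priors = pr, n_labeled = nrow(X),
                 n_unlabeled = if (is.null(unlabeled)) 0L else nrow(unlabeled),
                 correlation = correlation,
                 lambda_floor = lambda_floor, sigma_floor = sigma_floor,
                 train_X = X, train_y = y,
                 feature_names = colnames(X)),
            class = "improved_nb")
}

#' Score samples with a fitted improved naive Bayes model
#'
#' Returns the full per-sample breakdown: the whitened projections `beta`
#' (overall-standardized) and `gamma` (class-standardized), the
#' class-conditional scores `H`, and the prior-free membership scores `L`.
#'
#' @param model a fitted [improved_nb()] model.
#' @param X_new matrix of samples to score.
#' @return list with `beta` (samples x features), `gamma_by_class` (list of
#'   two such matrices), `H` (samples x 2, columns `"0"`, `"1"`; all-`NA`
#'   when the model has no priors) and `L` (samples x 2).
#' @export
score_samples <- function(model, X_new) {
  stopifnot(inherits(model, "improved_nb"))
  X_new <- as.matrix(X_new)
  Z <- predict(model$transform, X_new)
  B <- sweep(sweep(Z, 2, model$overall_means), 2, model$overall_sds, "/") %*%
    model$P
  lam <- model$lambda
  gamma_by_class <- list()
  H <- matrix(NA_real_, nrow(Z), 2, dimnames = list(NULL, c("0", "1")))
  L <- matrix(NA_real_, nrow(Z), 2, dimnames = list(NULL, c("0", "1")))
  b2 <- rowSums(sweep(B^2, 2, lam, "/"))
  for (k in c("0", "1")) {
    G <- sweep(sweep(Z, 2, model$class_means[k, ]), 2,
               model$class_sds[k, ], "/") %*% model$P
    gamma_by_class[[k]] <- G
    g2_2lam <- rowSums(sweep(G^2, 2, 2 * lam, "/"))
    if (!is.null(model$priors)) {
      H[, k] <- log(model$priors[[k]]) - (g2_2lam +
                                            sum(log(model$class_sds[k, ])))
    }
    L[, k] <- b2 - rowSums(sweep(G^2, 2, lam, "/"))
  }
  list(beta = B, gamma_by_class = gamma_by_class, H = H, L = L)
}

#' Predict from an improved naive Bayes model
#'
#' @param object a fitted [improved_nb()] model.
#' @param newdata matrix of samples; defaults to the training samples.
#' @param type `"class"`: argmax of `H` (requires priors; ties break toward
#'   non-effective); `"score"`: `H[,"1"] - H[,"0"]`, a monotone stand-in for
#'   the log posterior odds of the effective class; `"H"` / `"L"`: the raw
#'   score matrices; `"breakdown"`: everything (see [score_samples()]).
#' @param ... unused.
#' @return per `type`: integer labels, numeric scores, a matrix, or a list.
#' @export
predict.improved_nb <- function(object, newdata = NULL,
                                type = c("class", "score", "H", "L",
                                         "breakdown"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$train_X
  sc <- score_samples(object, newdata)
  if (type == "breakdown") return(sc)
  if (type == "L") return(sc$L)
  stop_if_not(!is.null(object$priors),
              "model has no priors; use type = 'L' or predict_by_threshold()")
  if (type == "H") return(sc$H)
  diff <- sc$H[, "1"] - sc$H[, "0"]
  if (type == "score") return(diff)
  as.integer(diff > 0)  # tie (diff == 0) -> non-effective
}

#' Threshold-based prediction from the prior-free L score
#'
#' When class priors are not meaningful, samples are ranked by the
#' membership score `L` for the target class and a cut-off is chosen on a
#' labeled calibration set from the ROC curve: by default the threshold
#' maximizing Youden's J (sensitivity + specificity - 1); alternatively the
#' point closest to the ideal (0, 1) corner.  Samples with `L >= threshold`
#' are assigned to the target class.
#'
#' @param model a fitted [improved_nb()] model.
#' @param newdata samples to classify.
#' @param target_class class whose membership is scored (default 1,
#'   effective).
#' @param rule `"youden"` or `"closest01"`.
#' @param threshold optional fixed threshold, bypassing calibration.
#' @param calibration list with elements `X` and `y` to calibrate on;
#'   defaults to the model's training data.
#' @return list with `labels` (1 = target class), `L` (scores for
#'   `newdata`) and `threshold`.
#' @export
predict_by_threshold <- function(model, newdata, target_class = 1,
                                 rule = c("youden", "closest01"),
                                 threshold = NULL, calibration = NULL) {
  rule <- match.arg(rule)
  k <- as.character(target_class)
  L_new <- score_samples(model, newdata)$L[, k]
  if (is.null(threshold)) {
    if (is.null(calibration)) {
      calibration <- list(X = model$train_X, y = model$train_y)
    }
    L_cal <- score_samples(model, calibration$X)$L[, k]
    is_target <- as.integer(as.character(calibration$y) == k)
    threshold <- choose_threshold(L_cal, is_target, rule)
  }
  list(labels = as.integer(L_new >= threshold), L = L_new,
       threshold = threshold)
}

#' Choose a score threshold from labeled calibration data
#'
#' Candidate thresholds are the observed score values (so shifting every
#' score by a constant shifts the chosen threshold by the same constant).
#' `"youden"` maximizes sensitivity + specificity - 1; `"closest01"`
#' minimizes the Euclidean distance to the ROC corner (0, 1).  Ties break
#' toward the larger (more conservative) threshold.
#'
#' @param scores numeric scores (larger = more target-like).
#' @param labels 1 for the target class, 0 otherwise; both must occur.
#' @param rule `"youden"` or `"closest01"`.
#' @return the chosen threshold (a value from `scores`).
#' @export
choose_threshold <- function(scores, labels, rule = c("youden", "closest01")) {
  rule <- match.arg(rule)
  labels <- as.integer(labels)
  stop_if_not(length(unique(labels)) == 2,
              "calibration labels must contain both classes")
  cand <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  crit <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1L) / npos
    spec <- sum(!pred & labels == 0L) / nneg
    if (rule == "youden") sens + spec - 1
    else -sqrt((1 - sens)^2 + (1 - spec)^2)
  }, numeric(1))
  best <- which(crit == max(crit))
  max(cand[best])
}

#' @export
print.improved_nb <- function(x, ...) {
  cat(sprintf(
    "Improved naive Bayes: %d features, %d labeled (+%d unlabeled) samples\n",
    ncol(x$train_X), x$n_labeled, x$n_unlabeled))
  cat(sprintf("  correlation basis: %s | priors: %s\n",
              if (x$correlation) "feature correlation eigenbasis"
              else "identity (Gaussian NB reduction)",
              if (is.null(x$priors)) "none"
              else paste(sprintf("P(%s)=%.3f", names(x$priors), x$priors),
                         collapse = ", ")))
  invisible(x)
}

#' @export
summary.improved_nb <- function(object, ...) {
  lam <- object$lambda
  out <- list(n_features = ncol(object$train_X),
              n_labeled = object$n_labeled,
              n_unlabeled = object$n_unlabeled,
              priors = object$priors,
              lambda_range = range(lam),
              lambda_top = utils::head(sort(lam, decreasing = TRUE), 5),
              mean_abs_offdiag_cor =
                mean(abs(object$R[upper.tri(object$R)])))
  class(out) <- "summary.improved_nb"
  out
}

#' @export
print.summary.improved_nb <- function(x, ...) {
  cat(sprintf("Improved naive Bayes fit on %d labeled + %d unlabeled samples, %d features\n",
              x$n_labeled, x$n_unlabeled, x$n_features))
  cat(sprintf("  mean |off-diagonal correlation|: %.3f\n",
              x$mean_abs_offdiag_cor))
  cat(sprintf("  eigenvalue range: [%.4f, %.4f]; leading: %s\n",
              x$lambda_range[1], x$lambda_range[2],
              paste(signif(x$lambda_top, 4), collapse = ", ")))
  if (!is.null(x$priors)) {
    cat(sprintf("  priors: P(0)=%.3f, P(1)=%.3f\n",
                x$priors[["0"]], x$priors[["1"]]))
  }
  invisible(x)
}

#' @export
coef.improved_nb <- function(object, ...) {
  list(class_means = object$class_means, class_sds = object$class_sds,
       overall_means = object$overall_means,
       overall_sds = object$overall_sds, priors = object$priors)
}

#' Simulate from the model's generative assumptions
#'
#' Draws labeled samples in the transformed feature space: a class from the
#' priors, then a Gaussian vector with that class's means/SDs and the fitted
#' correlation structure (`Sigma_k = D_k R D_k`).  Useful for parameter-
#' recovery checks; note the output lives on the transformed (normal-score)
#' scale, not the raw count scale.
#'
#' @param object a fitted [improved_nb()] model (with priors).
#' @param nsim number of samples.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list with `X` (nsim x features matrix, transformed scale) and `y`.
#' @export
simulate.improved_nb <- function(object, nsim = 1, seed = NULL, ...) {
  stop_if_not(!is.null(object$priors), "simulation requires priors")
  with_seed(seed, {
    p <- ncol(object$train_X)
    U <- chol(object$R + diag(1e-10, p))
    y <- stats::rbinom(nsim, 1, object$priors[["1"]])
    Zstd <- matrix(stats::rnorm(nsim * p), nsim, p) %*% U
    k <- as.character(y)
    X <- Zstd * object$class_sds[k, , drop = FALSE] +
      object$class_means[k, , drop = FALSE]
    list(X = X, y = y)
  })
}
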