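#' Serialize an improved naive Bayes model to JSON
#'
#' The file records the transform knots, correlation matrix, eigenbasis,
#' class and overall moments, priors and configuration at full double
#' precision, so a reloaded model reproduces scores to better than 1e-12.
#'
#' @param model a fitted [improved_nb()] model.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_improved_nb <- function(model, path) {
  stopifnot(inherits(model, "improved_nb"))
  obj <- list(
    format = "combiNB/improved_nb",
    version = 1L,
    transform = list(
      maps = lapply(model$transform$maps,
                    function(m) list(value = m$value, score = m$score)),
      n = model$transform$n,
      constant = model$transform$constant),
    R = model$R, lambda = model$lambda, P = model$P,
    class_means = model$class_means, class_sds = model$class_sds,
    overall_means = model$overall_means, overall_sds = model$overall_sds,
    priors = model$priors,
    n_labeled = model$n_labeled, n_unlabeled = model$n_unlabeled,
    correlation = model$correlation,
    lambda_floor = model$lambda_floor, sigma_floor = model$sigma_floor,
    train_X = model$train_X, train_y = model$train_y,
    feature_names = model$feature_names)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              null = "null", matrix = "rowmajor"),
             path)
  invisible(path)
}

#' @rdname write_improved_nb
#' @return `read_improved_nb()` returns the reconstructed `improved_nb`
#'   model.
#' @export
read_improved_nb <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  stop_if_not(identical(obj$format, "combiNB/improved_nb"),
              "not a serialized improved_nb model")
  as_num_matrix <- function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  }
  transform <- structure(
    list(maps = lapply(obj$transform$maps,
                       function(m) list(value = as.numeric(m$value),
                                        score = as.numeric(m$score))),
         n = obj$transform$n,
         constant = as.logical(obj$transform$constant),
         colnames = obj$feature_names),
    class = "normal_transform")
  cm <- as_num_matrix(obj$class_means); rownames(cm) <- c("0", "1")
  cs <- as_num_matrix(obj$class_sds); rownames(cs) <- c("0", "1")
  pr <- if (is.null(obj$priors)) NULL else {
    p <- as.numeric(unlist(obj$priors)); names(p) <- c("0", "1"); p
  }
  tx <- as_num_matrix(obj$train_X)
  if (!is.null(obj$feature_names)) colnames(tx) <- obj$feature_names
  structure(list(transform = transform,
                 R = as_num_matrix(obj$R),
                 lambda = as.numeric(obj$lambda),
                 P = as_num_matrix(obj$P),
                 class_means = cm, class_sds = cs,
                 overall_means = as.numeric(obj$overall_means),
                 overall_sds = as.numeric(obj$overall_sds),
                 priors = pr,
                 n_labeled = obj$n_labeled, n_unlabeled = obj$n_unlabeled,
                 correlation = obj$correlation,
                 lambda_floor = obj$lambda_floor,
                 sigma_floor = obj$sigma_floor,
                 train_X = tx, train_y = as.integer(obj$train_y),
                 feature_names = obj$feature_names),
            class = "improved_nb")
}
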