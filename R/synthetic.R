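#' Configuration for synthetic drug-combination studies
#'
#' Describes a synthetic drug universe and pair study with the statistical
#' structure the classifier assumes: sparse per-drug binary (or dose-coded)
#' features generated from a latent Gaussian copula with block correlation,
#' and a class signal planted directly in the pair-level feature
#' distribution.
#'
#' @param n_drugs number of drugs in the universe.
#' @param n_features feature dimension.
#' @param category feature category (side effects get dose codes 0/1/2).
#' @param prevalence per-feature Bernoulli rates: either a length-2 range
#'   from which rates are drawn uniformly, or a vector of `n_features`
#'   rates.
#' @param block_size,block_rho latent correlation structure: features come
#'   in blocks of `block_size` sharing a latent factor with loading
#'   `sqrt(block_rho)` (within-block latent correlation `block_rho`).
#' @param n_informative number of informative features (spread evenly
#'   across the blocks).
#' @param effect_size difference in pair-level presence frequency between
#'   effective and non-effective pairs on informative features, so that the
#'   screening gap `p2 - p1` is `effect_size / 2` at a 1:1 class ratio.
#' @param n_positive_pairs number of effective pairs.
#' @param negative_ratio negatives per positive (default 1).
#' @param unlabeled_pool_size number of unlabeled candidate pairs.
#' @param seed integer seed; every generated artifact is a deterministic
#'   function of the config including the seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 150, n_features = 200,
                             category = "target",
                             prevalence = c(0.05, 0.25),
                             block_size = 10, block_rho = 0.3,
                             n_informative = 10, effect_size = 0.3,
                             n_positive_pairs = 200, negative_ratio = 1,
                             unlabeled_pool_size = 400, seed = NULL) {
  stop_if_not(effect_size >= 0 && effect_size <= 1,
              "effect_size must lie in [0, 1]")
  stop_if_not(n_informative <= n_features,
              "n_informative cannot exceed n_features")
  stop_if_not(block_rho >= 0 && block_rho < 1,
              "block_rho must lie in [0, 1)")
  stop_if_not(all(prevalence > 0 & prevalence < 1),
              "prevalences must lie strictly in (0, 1)")
  stop_if_not(length(prevalence) %in% c(2L, n_features),
              "prevalence must be a range or one rate per feature")
  structure(list(n_drugs = n_drugs, n_features = n_features,
                 category = category, prevalence = prevalence,
                 block_size = block_size, block_rho = block_rho,
                 n_informative = n_informative, effect_size = effect_size,
                 n_positive_pairs = n_positive_pairs,
                 negative_ratio = negative_ratio,
                 unlabeled_pool_size = unlabeled_pool_size, seed = seed),
            class = "synthetic_config")
}

#' Feature-dimension presets mirroring real extraction runs
#'
#' Named presets carrying the feature dimensionalities observed in real
#' per-category extractions for the two negative-set constructions (N1:
#' drugs restricted to positive pairs; N2: the whole catalogue), e.g.
#' enzymes 135/146, side effects 3005/3889.
#'
#' @param category feature category.
#' @param negative_set `"N1"` or `"N2"`.
#' @param ... overrides forwarded to [synthetic_config()].
#' @return a [synthetic_config()] with the preset feature dimension.
#' @export
synthetic_preset <- function(category = c("target", "pathway", "enzyme",
                                          "transporter", "side_effect"),
                             negative_set = c("N1", "N2"), ...) {
  category <- match.arg(category)
  negative_set <- match.arg(negative_set)
  dims <- list(target = c(N1 = 681, N2 = 787),
               pathway = c(N1 = 255, N2 = 263),
               enzyme = c(N1 = 135, N2 = 146),
               transporter = c(N1 = 76, N2 = 86),
               side_effect = c(N1 = 3005, N2 = 3889))
  synthetic_config(n_features = unname(dims[[category]][negative_set]),
                   category = category, ...)
}

#' Generate a synthetic drug universe
#'
#' Per-drug feature vectors are thresholded from a latent Gaussian with
#' block correlation: drug d's latent value for feature j in block b is
#' `sqrt(rho) * u_db + sqrt(1 - rho) * e_dj`, dichotomized at the normal
#' quantile matching that feature's target prevalence.  Side-effect
#' categories emit dose codes 0/1/2 with the prevalence split evenly
#' between low- and high-dose occurrence.
#'
#' @param cfg a [synthetic_config()].
#' @return a [drug_feature_table()] with attribute `"prevalence"` (the
#'   target rates used).
#' @export
generate_drug_universe <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    p <- cfg$n_features; nd <- cfg$n_drugs
    prev <- if (length(cfg$prevalence) == 2L) {
      stats::runif(p, min(cfg$prevalence), max(cfg$prevalence))
    } else cfg$prevalence
    block <- ((seq_len(p) - 1L) %/% cfg$block_size) + 1L
    nb <- max(block)
    U <- matrix(stats::rnorm(nd * nb), nd, nb)
    E <- matrix(stats::rnorm(nd * p), nd, p)
    Z <- sqrt(cfg$block_rho) * U[, block, drop = FALSE] +
      sqrt(1 - cfg$block_rho) * E
    if (identical(cfg$category, "side_effect")) {
      t1 <- stats::qnorm(1 - prev)        # any occurrence
      t2 <- stats::qnorm(1 - prev / 2)    # high-dose occurrence
      M <- (Z > rep(t1, each = nd)) + (Z > rep(t2, each = nd))
    } else {
      M <- (Z > rep(stats::qnorm(1 - prev), each = nd)) * 1L
    }
    storage.mode(M) <- "integer"
    dimnames(M) <- list(sprintf("D%04d", seq_len(nd)),
                        sprintf("f%04d", seq_len(p)))
    tab <- drug_feature_table(M, cfg$category)
    attr(tab, "prevalence") <- prev
    tab
  })
}

## distinct unordered pairs over `drugs`, excluding `exclude_keys`;
## assumes the RNG is already seeded by the caller
sample_pairs_internal <- function(drugs, n, exclude_keys = character(0)) {
  k <- length(drugs)
  stop_if_not(choose(k, 2) - length(exclude_keys) >= n,
              "requested more pairs than the universe can supply")
  idx <- utils::combn(k, 2)
  keys <- pair_key(drugs[idx[1, ]], drugs[idx[2, ]])
  pool <- which(!(keys %in% exclude_keys))
  take <- pool[sample.int(length(pool), n)]
  out <- data.frame(drug_a = pmin(drugs[idx[1, take]], drugs[idx[2, take]]),
                    drug_b = pmax(drugs[idx[1, take]], drugs[idx[2, take]]),
                    stringsAsFactors = FALSE)
  class(out) <- c("drug_pairs", "data.frame")
  out
}

#' Generate a labeled synthetic pair study
#'
#' Builds the full study a real extraction would yield: a drug universe,
#' effective (positive) pairs, sampled non-effective (negative) pairs, an
#' unlabeled candidate pool, and sum-encoded feature vectors.  The class
#' signal is planted at the pair level: on each informative feature the
#' positive pairs' presence indicator is resampled to frequency
#' `q_neg + effect_size` (capped at 1), where `q_neg` is the feature's
#' presence frequency among negative pairs, so that after binarization the
#' screening gap `|p2 - p1|` is `effect_size / 2` at a 1:1 ratio while null
#' features drift only by sampling noise.
#'
#' @param cfg a [synthetic_config()].
#' @param strategy negative-sampling strategy (`"N2"` draws from the whole
#'   universe, `"N1"` from drugs occurring in positives).
#' @return list of class `pair_study`: `dataset` (a `pair_dataset` whose
#'   unlabeled rows have `NA` labels), `universe`, `informative` (planted
#'   feature indices) and `config`.
#' @export
generate_pair_study <- function(cfg, strategy = c("N2", "N1")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  strategy <- match.arg(strategy)
  universe <- generate_drug_universe(cfg)
  with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, {
    drugs <- universe$drug_ids
    pos <- sample_pairs_internal(drugs, cfg$n_positive_pairs)
    pos_keys <- pair_key(pos$drug_a, pos$drug_b)
    neg_drugs <- if (strategy == "N1") {
      sort(unique(c(pos$drug_a, pos$drug_b)))
    } else drugs
    neg <- sample_pairs_internal(neg_drugs,
                                 cfg$negative_ratio * cfg$n_positive_pairs,
                                 exclude_keys = pos_keys)
    used <- c(pos_keys, pair_key(neg$drug_a, neg$drug_b))
    unl <- if (cfg$unlabeled_pool_size > 0) {
      sample_pairs_internal(drugs, cfg$unlabeled_pool_size,
                            exclude_keys = used)
    } else NULL
    ds <- build_pair_dataset(universe, pos, neg, unlabeled = unl)

    informative <- sort(unique(round(seq(1, cfg$n_features,
                                         length.out = cfg$n_informative))))
    ## plant the pair-level signal: resample the presence indicator of each
    ## informative feature on positive rows at q_neg + effect_size
    pos_rows <- which(ds$y == 1L)
    neg_rows <- which(ds$y == 0L)
    for (j in informative) {
      q_neg <- mean(ds$X[neg_rows, j] != 0L)
      q_pos <- min(1, q_neg + cfg$effect_size)
      on <- stats::rbinom(length(pos_rows), 1L, q_pos) == 1L
      v <- ds$X[pos_rows, j]
      v[!on] <- 0L
      v[on & v == 0L] <- 1L
      ds$X[pos_rows, j] <- v
    }
    structure(list(dataset = ds, universe = universe,
                   informative = informative, config = cfg,
                   strategy = strategy),
              class = "pair_study")
  })
}

#' @export
print.pair_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic pair study ('%s', %s negatives): %d informative of %d features, effect %.2f\n",
    x$config$category, x$strategy, length(x$informative),
    x$config$n_features, x$config$effect_size))
  print(x$dataset)
  invisible(x)
}

## convenience accessors for the labeled block of a study
study_labeled <- function(study) {
  ds <- study$dataset
  idx <- which(!is.na(ds$y))
  list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx])
}

study_unlabeled <- function(study) {
  ds <- study$dataset
  idx <- which(is.na(ds$y))
  if (!length(idx)) NULL else ds$X[idx, , drop = FALSE]
}

#' Export a synthetic study in the standard pair formats
#'
#' Writes the universe table, the pair dataset TSV + JSON sidecar (with the
#' config and seed recorded), and the positive/negative pair lists.
#'
#' @param study a [generate_pair_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_pair_study <- function(study, dir) {
  stopifnot(inherits(study, "pair_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  paths <- c(paths, write_drug_table(study$universe,
                                     file.path(dir, "universe.tsv")))
  cfg <- study$config
  paths <- c(paths,
             export_pair_dataset(study$dataset, file.path(dir, "pairs"),
                                 provenance = c(unclass(cfg),
                                                list(strategy = study$strategy,
                                                     informative = study$informative))))
  ds <- study$dataset
  for (lbl in c(1L, 0L)) {
    pp <- ds$pairs[!is.na(ds$y) & ds$y == lbl, , drop = FALSE]
    f <- file.path(dir, if (lbl == 1L) "positives.tsv" else "negatives.tsv")
    paths <- c(paths, write_pair_list(pp, f))
  }
  invisible(paths)
}

#' Generate a correlated-Gaussian classification study
#'
#' Draws labeled (and optionally unlabeled) samples from the classifier's
#' own generative regime: features share a latent factor within blocks
#' (pairwise within-block correlation `rho`), and the class signal sits on
#' the first feature of every block — a mean shift of `+delta` for the
#' effective class and `-delta` for the non-effective class — so the signal
#' is spread across correlated blocks while each block's remaining features
#' act as correlated nuisance.  This is the regime where modelling the
#' feature correlation pays: a diagonal (naive) Gaussian model cannot use
#' the null block-mates to cancel the shared-factor noise.
#'
#' @param n number of labeled samples (balanced 1:1).
#' @param n_unlabeled unlabeled samples drawn from the same class mixture.
#' @param n_features feature dimension (a multiple of `block_size`).
#' @param block_size features per correlated block.
#' @param rho pairwise within-block correlation.
#' @param delta class mean shift on the informative features.
#' @param seed integer seed.
#' @return list with `X`, `y`, `unlabeled`, `informative` (indices of the
#'   shifted features).
#' @export
generate_gaussian_study <- function(n = 100, n_unlabeled = 200,
                                    n_features = 30, block_size = 10,
                                    rho = 0.6, delta = 0.3, seed = NULL) {
  stop_if_not(n_features %% block_size == 0,
              "n_features must be a multiple of block_size")
  stop_if_not(n %% 2 == 0 && (n_unlabeled %% 2 == 0),
              "sample counts must be even (balanced classes)")
  with_seed(seed, {
    nb <- n_features %/% block_size
    block <- rep(seq_len(nb), each = block_size)
    informative <- which(rep(seq_len(block_size), nb) == 1L)
    mu1 <- numeric(n_features); mu1[informative] <- delta
    draw <- function(m, mu) {
      U <- matrix(stats::rnorm(m * nb), m, nb)
      E <- matrix(stats::rnorm(m * n_features), m, n_features)
      sweep(sqrt(rho) * U[, block, drop = FALSE] + sqrt(1 - rho) * E,
            2, mu, "+")
    }
    X <- rbind(draw(n / 2, -mu1), draw(n / 2, mu1))
    y <- rep(c(0L, 1L), each = n / 2)
    unl <- if (n_unlabeled > 0) {
      rbind(draw(n_unlabeled / 2, -mu1), draw(n_unlabeled / 2, mu1))
    } else NULL
    list(X = X, y = y, unlabeled = unl, informative = informative)
  })
}
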