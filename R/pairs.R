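#' Canonicalize a set of unordered drug pairs
#'
#' Pairs are stored canonically as `(min_id, max_id)` in lexicographic order,
#' so pair equality is order-insensitive and exclusion checks against the
#' positive set are well defined.
#'
#' @param x a two-column data frame / matrix of drug identifiers, or a
#'   character vector of length 2 for a single pair.
#' @return a data frame with character columns `drug_a`, `drug_b`
#'   (`drug_a < drug_b`), class `drug_pairs`.
#' @export
as_drug_pairs <- function(x) {
  if (is.character(x) && length(x) == 2L) x <- matrix(x, nrow = 1)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stop_if_not(ncol(x) >= 2L, "pairs need two identifier columns")
  a <- as.character(x[[1]]); b <- as.character(x[[2]])
  stop_if_not(!any(a == b), "a drug cannot be paired with itself")
  out <- data.frame(drug_a = pmin(a, b), drug_b = pmax(a, b),
                    stringsAsFactors = FALSE)
  class(out) <- c("drug_pairs", "data.frame")
  out
}

n_pairs <- function(p) nrow(p)

#' Encode a drug pair by elementwise summation
#'
#' The pair feature vector is the elementwise sum of the two drugs' vectors:
#' entries 0/1/2 for binary categories, 0..4 for dose-coded side effects.
#' Symmetric in its arguments.
#'
#' @param a_vec,b_vec integer feature vectors of equal length.
#' @param category feature category, used for range validation.
#' @return integer vector of elementwise sums.
#' @examples
#' encode_pair(c(1, 0, 1), c(1, 1, 0))            # 2 1 1
#' encode_pair(c(2, 0), c(2, 1), "side_effect")   # 4 1
#' @export
encode_pair <- function(a_vec, b_vec, category = "target") {
  stop_if_not(length(a_vec) == length(b_vec),
              "pair members must have the same feature length")
  vmax <- drug_value_max(category)
  ok <- function(v) all(v >= 0 & v <= vmax & v == round(v))
  stop_if_not(ok(a_vec) && ok(b_vec),
              sprintf("entries must lie in 0..%d for category '%s'",
                      vmax, category))
  as.integer(a_vec) + as.integer(b_vec)
}

#' Build a labeled drug-pair dataset
#'
#' Encodes each pair by [encode_pair()] over the rows of `table` and attaches
#' labels: 1 for effective (positive) pairs, 0 for non-effective (negative)
#' pairs, `NA` for unlabeled candidate pairs.  Pairs referencing a drug
#' absent from the table are dropped and counted, mirroring the
#' availability filter used when assembling real feature groups.
#'
#' @param table a [drug_feature_table()].
#' @param positives,negatives,unlabeled pair sets coercible via
#'   [as_drug_pairs()]; `negatives` and `unlabeled` may be `NULL`.
#' @return an object of class `pair_dataset`: list with `pairs` (canonical
#'   pair data frame), `X` (pairs x features integer matrix), `y` (1/0/NA),
#'   `category`, and `n_dropped`.
#' @export
build_pair_dataset <- function(table, positives, negatives = NULL,
                               unlabeled = NULL) {
  stopifnot(inherits(table, "drug_feature_table"))
  pos <- as_drug_pairs(positives)
  neg <- if (is.null(negatives) || NROW(negatives) == 0) NULL
         else as_drug_pairs(negatives)
  unl <- if (is.null(unlabeled) || NROW(unlabeled) == 0) NULL
         else as_drug_pairs(unlabeled)
  if (!is.null(neg)) {
    clash <- intersect(pair_key(pos$drug_a, pos$drug_b),
                       pair_key(neg$drug_a, neg$drug_b))
    stop_if_not(length(clash) == 0,
                "a pair cannot be both positive and negative")
  }
  pairs <- rbind(pos,
                 if (!is.null(neg)) neg,
                 if (!is.null(unl)) unl)
  y <- c(rep(1L, nrow(pos)),
         if (!is.null(neg)) rep(0L, nrow(neg)),
         if (!is.null(unl)) rep(NA_integer_, nrow(unl)))

  present <- pairs$drug_a %in% table$drug_ids & pairs$drug_b %in% table$drug_ids
  n_dropped <- sum(!present)
  if (n_dropped > 0) {
    message(sprintf("dropped %d pair(s) with a drug missing from the table",
                    n_dropped))
    pairs <- pairs[present, , drop = FALSE]
    y <- y[present]
  }
  stop_if_not(nrow(pairs) > 0, "no pair has both drugs in the table")

  m <- table$matrix
  X <- m[pairs$drug_a, , drop = FALSE] + m[pairs$drug_b, , drop = FALSE]
  storage.mode(X) <- "integer"
  rownames(X) <- pair_key(pairs$drug_a, pairs$drug_b)

  ## a pair duplicated across the label groups would carry two labels
  dup <- duplicated(rownames(X))
  if (any(dup)) {
    keys <- rownames(X)[dup]
    lab <- y[rownames(X) %in% keys]
    stop_if_not(length(unique(lab[!is.na(lab)])) <= 1,
                "the same pair appears with two different labels")
    pairs <- pairs[!dup, , drop = FALSE]
    X <- X[!dup, , drop = FALSE]
    y <- y[!dup]
  }

  structure(list(pairs = pairs, X = X, y = y, category = table$category,
                 n_dropped = n_dropped),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf(
    "Pair dataset ('%s'): %d pairs x %d features | %d effective, %d non-effective, %d unlabeled\n",
    x$category, nrow(x$X), ncol(x$X),
    sum(x$y == 1L, na.rm = TRUE), sum(x$y == 0L, na.rm = TRUE),
    sum(is.na(x$y))))
  if (x$n_dropped > 0) cat(sprintf("  (%d pair(s) dropped: missing drugs)\n",
                                   x$n_dropped))
  invisible(x)
}

## rows of a pair_dataset restricted to labeled samples
labeled_rows <- function(ds) which(!is.na(ds$y))

#' Sample negative (non-effective) drug pairs
#'
#' Two strategies for constructing benchmark negatives:
#' * `"N1"`: random pairs of drugs that occur in the positive pairs;
#' * `"N2"`: random pairs drawn from a supplied drug universe (e.g. the whole
#'   catalogue).
#'
#' No sampled pair ever equals a known positive pair, self-pairs are
#' excluded, and the `n` returned pairs are distinct.  Sampling is
#' reproducible for a given `seed`.
#'
#' @param strategy `"N1"` or `"N2"`.
#' @param positives positive pairs ([as_drug_pairs()]-coercible).
#' @param universe character vector of drug ids (required for `"N2"`,
#'   ignored for `"N1"`).
#' @param n number of pairs to draw.
#' @param seed integer seed.
#' @return a canonical `drug_pairs` data frame of `n` pairs.
#' @export
generate_negative_pairs <- function(strategy = c("N1", "N2"), positives,
                                    universe = NULL, n, seed = NULL) {
  strategy <- match.arg(strategy)
  pos <- as_drug_pairs(positives)
  drugs <- if (strategy == "N1") {
    sort(unique(c(pos$drug_a, pos$drug_b)))
  } else {
    stop_if_not(!is.null(universe), "strategy N2 requires a drug universe")
    sort(unique(as.character(universe)))
  }
  k <- length(drugs)
  pos_keys <- unique(pair_key(pos$drug_a, pos$drug_b))
  avail <- choose(k, 2) - length(pair_key_grid_membership(pos_keys, drugs))
  stop_if_not(n <= avail,
              sprintf("requested %d pairs but only %d non-positive pairs exist",
                      n, avail))

  with_seed(seed, {
    if (choose(k, 2) <= 2e5) {
      idx <- utils::combn(k, 2)
      all_keys <- pair_key(drugs[idx[1, ]], drugs[idx[2, ]])
      keep <- !(all_keys %in% pos_keys)
      pool <- which(keep)
      take <- pool[sample.int(length(pool), n)]
      out <- data.frame(drug_a = pmin(drugs[idx[1, take]], drugs[idx[2, take]]),
                        drug_b = pmax(drugs[idx[1, take]], drugs[idx[2, take]]),
                        stringsAsFactors = FALSE)
    } else {
      ## rejection sampling for large universes
      seen <- character(0)
      out_a <- character(n); out_b <- character(n); got <- 0L
      while (got < n) {
        m <- max(2L * (n - got), 64L)
        ia <- sample.int(k, m, replace = TRUE)
        ib <- sample.int(k, m, replace = TRUE)
        ok <- ia != ib
        a <- drugs[ia[ok]]; b <- drugs[ib[ok]]
        key <- pair_key(a, b)
        fresh <- !(key %in% pos_keys) & !(key %in% seen) & !duplicated(key)
        a <- a[fresh]; b <- b[fresh]; key <- key[fresh]
        take <- seq_len(min(length(key), n - got))
        if (length(take)) {
          out_a[got + take] <- pmin(a[take], b[take])
          out_b[got + take] <- pmax(a[take], b[take])
          seen <- c(seen, key[take])
          got <- got + length(take)
        }
      }
      out <- data.frame(drug_a = out_a, drug_b = out_b,
                        stringsAsFactors = FALSE)
    }
    class(out) <- c("drug_pairs", "data.frame")
    out
  })
}

## positive keys that actually lie inside the sampling grid (both drugs drawn
## from `drugs`); only those reduce the available pair count
pair_key_grid_membership <- function(pos_keys, drugs) {
  parts <- strsplit(pos_keys, "\r", fixed = TRUE)
  inside <- vapply(parts, function(p) all(p %in% drugs), logical(1))
  pos_keys[inside]
}

#' Feature-coverage summary for drug pairs
#'
#' For every nonempty subset of feature categories, counts how many of the
#' given pairs have both drugs present in all of the subset's drug sets —
#' the tabular analogue of a coverage Venn diagram.
#'
#' @param tables named list; each element a [drug_feature_table()] or a
#'   character vector of drug ids for one category.
#' @param pairs pairs coercible via [as_drug_pairs()].
#' @return data frame with columns `categories` (\code{+}-separated subset
#'   label), `n_categories` and `count`, ordered by subset size.
#' @export
coverage_summary <- function(tables, pairs) {
  stop_if_not(length(names(tables)) == length(tables) &&
                all(nzchar(names(tables))), "tables must be a named list")
  sets <- lapply(tables, function(t) {
    if (inherits(t, "drug_feature_table")) t$drug_ids else as.character(t)
  })
  p <- as_drug_pairs(pairs)
  covered <- vapply(sets, function(s) p$drug_a %in% s & p$drug_b %in% s,
                    logical(nrow(p)))
  covered <- matrix(covered, nrow = nrow(p),
                    dimnames = list(NULL, names(sets)))
  cats <- names(sets)
  out <- do.call(rbind, lapply(seq_along(cats), function(sz) {
    combos <- utils::combn(cats, sz, simplify = FALSE)
    do.call(rbind, lapply(combos, function(cc) {
      data.frame(categories = paste(cc, collapse = "+"),
                 n_categories = sz,
                 count = sum(rowSums(covered[, cc, drop = FALSE]) == sz),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write pair lists
#'
#' Two-column tab-separated drug-id lists, optionally with a third 0/1 label
#' column.
#'
#' @param path file path.
#' @return `read_pair_list()`: a canonical `drug_pairs` data frame, with a
#'   `label` column if present in the file.
#' @export
read_pair_list <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- as_drug_pairs(df[, 1:2])
  if (ncol(df) >= 3) out$label <- as.integer(df[[3]])
  out
}

#' @param pairs pairs to write; a `label` column is written when present.
#' @rdname read_pair_list
#' @export
write_pair_list <- function(pairs, path) {
  p <- as_drug_pairs(pairs)
  if (!is.null(pairs$label)) p$label <- pairs$label
  utils::write.table(p, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a pair dataset as TSV plus a JSON sidecar
#'
#' Writes `<prefix>.tsv` (drug ids, encoded features, label) and
#' `<prefix>.json` (category, dimensions, drop count, optional provenance).
#'
#' @param ds a `pair_dataset`.
#' @param prefix output path prefix.
#' @param provenance optional list stored verbatim in the sidecar.
#' @return invisibly, the two paths written.
#' @export
export_pair_dataset <- function(ds, prefix, provenance = NULL) {
  stopifnot(inherits(ds, "pair_dataset"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  df <- data.frame(ds$pairs, ds$X, label = ds$y, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(category = ds$category, n_pairs = nrow(ds$X),
               n_features = ncol(ds$X), n_dropped = ds$n_dropped,
               provenance = provenance)
  jsonlite::write_json(side, json, auto_unbox = TRUE, null = "null")
  invisible(c(tsv, json))
}
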