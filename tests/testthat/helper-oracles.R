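# Independent oracles used across the suite; none of these call package
# internals for the quantity they check.

# AUC as the Mann-Whitney concordant-pair statistic (half credit for ties).
auc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Mutual information by the entropy identity H(X) + H(Y) - H(X, Y).
mi_bruteforce <- function(x, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  ent(x) + ent(y) - ent(paste(x, y))
}

# Small deterministic 5-drug binary table.
make_toy_table <- function() {
  m <- matrix(c(1, 0, 1, 0,
                0, 1, 1, 0,
                1, 1, 0, 0,
                0, 0, 1, 1,
                1, 0, 0, 1),
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("D", 1:5), paste0("f", 1:4)))
  drug_feature_table(m, "target")
}

# All unordered pairs over ids, as a canonical data frame.
all_pairs_of <- function(ids) {
  idx <- utils::combn(ids, 2)
  as_drug_pairs(data.frame(a = idx[1, ], b = idx[2, ]))
}

pair_keys_of <- function(p) paste(pmin(p$drug_a, p$drug_b),
                                  pmax(p$drug_a, p$drug_b))
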