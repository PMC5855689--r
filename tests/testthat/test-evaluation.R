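test_that("metrics reproduce the published worked example", {
  # 1:1 independent test of the dose-coded side-effect group:
  # TP=16, TN=18, FP=7, FN=9
  rep1 <- compute_metrics(structure(list(TP = 16L, TN = 18L, FP = 7L,
                                         FN = 9L),
                                    class = "confusion_matrix"))
  expect_equal(round_half_up(rep1$accuracy), 0.6800)
  expect_equal(round_half_up(rep1$recall), 0.6400)
  expect_equal(round_half_up(rep1$precision), 0.6957)
  expect_equal(round_half_up(rep1$f_measure), 0.6667)
  expect_equal(round_half_up(rep1$mcc), 0.3612)
})

test_that("degenerate confusion matrices use the documented conventions", {
  all_pos <- compute_metrics(confusion_matrix(rep(1, 5), rep(1, 5)))
  expect_equal(unlist(all_pos[c("accuracy", "recall", "specificity",
                                "precision", "f_measure")]),
               c(accuracy = 1, recall = 1, specificity = 1, precision = 1,
                 f_measure = 1))
  expect_equal(all_pos$mcc, 0)  # undefined denominator -> 0

  sym <- compute_metrics(structure(list(TP = 5L, TN = 5L, FP = 5L, FN = 5L),
                                   class = "confusion_matrix"))
  expect_equal(sym$accuracy, 0.5)
  expect_equal(sym$mcc, 0)
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(77)
  for (i in 1:50) {
    cm <- structure(as.list(setNames(rpois(4, 20) + 1,
                                     c("TP", "TN", "FP", "FN"))),
                    class = "confusion_matrix")
    m <- compute_metrics(cm)
    # F-measure is the harmonic mean of recall and precision
    expect_equal(m$f_measure,
                 2 / (1 / m$recall + 1 / m$precision), tolerance = 1e-12)
    # MCC is invariant under swapping TP<->TN and FP<->FN
    sw <- compute_metrics(structure(list(TP = cm$TN, TN = cm$TP,
                                         FP = cm$FN, FN = cm$FP),
                                    class = "confusion_matrix"))
    expect_equal(m$mcc, sw$mcc, tolerance = 1e-12)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("ROC/AUC equals the concordant-pair oracle, including ties", {
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(19)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_lt(abs(r$auc - auc_bruteforce(scores, labels)), 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[c(1, nrow(r$points))], c(0, 1))
  }

  # independent library cross-check on one instance
  set.seed(20)
  s <- rnorm(80); l <- rbinom(80, 1, 0.5)
  expect_equal(roc_auc(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, direction = "<",
                                              levels = c("0", "1"),
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("LOOCV equals exhaustive nearest-neighbour agreement for 1-NN", {
  set.seed(33)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0L, 1L), 10)
  res <- loocv(classifier_spec("knn", k = 1, l = 0), X, y, selector = "none")
  brute <- vapply(1:20, function(i) {
    d <- sqrt(colSums((t(X[-i, ]) - X[i, ])^2))
    y[-i][which.min(d)]
  }, integer(1))
  expect_equal(res$labels, brute)
  expect_equal(res$metrics$accuracy, mean(brute == y))

  # minimal run: 3 samples needs a 2-sample-per-class guard relaxed via knn
  res3 <- suppressWarnings(loocv(classifier_spec("knn", k = 1, l = 0),
                                 matrix(c(0, 0, 5, 5.1, 9, 9), 3), c(0, 1, 1),
                                 selector = "none"))
  expect_equal(sum(!is.na(res3$scores)), 3)
})

test_that("label permutation drives LOOCV AUC to chance", {
  set.seed(55)
  aucs <- vapply(1:20, function(s) {
    set.seed(500 + s)
    X <- matrix(rbinom(40 * 6, 1, 0.4), 40)
    y <- sample(rep(c(0L, 1L), 20))   # labels independent of X
    loocv(classifier_spec("categorical_nb"), X, y, selector = "none")$roc$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("train/test splitting follows the floor rule and the seed", {
  sp <- split_train_test(202, 0.75, seed = 4)
  expect_length(sp$train, 151)
  expect_length(sp$test, 51)
  expect_identical(sp, split_train_test(202, 0.75, seed = 4))
  expect_false(identical(sp$train, split_train_test(202, 0.75, seed = 5)$train))
  expect_setequal(c(sp$train, sp$test), 1:202)

  sp2 <- split_train_test(2, 0.5)
  expect_length(sp2$train, 1); expect_length(sp2$test, 1)
  expect_error(split_train_test(3, 0.1), "nonempty")
  expect_error(split_train_test(10, 1.2), "between 0 and 1")
})

test_that("ratio sweeps scale the negative set and detect planted signal", {
  # drug-level signal: "hub" drugs carry the first 5 features, positives
  # pair hubs, so the signal survives re-encoding from the table
  set.seed(61)
  n_drugs <- 60
  m <- matrix(rbinom(n_drugs * 30, 1, 0.1), n_drugs, 30,
              dimnames = list(sprintf("D%02d", 1:n_drugs), NULL))
  hubs <- 1:30
  m[hubs, 1:5] <- matrix(rbinom(30 * 5, 1, 0.8), 30, 5)
  tab <- drug_feature_table(m, "target")
  pos <- as_drug_pairs(t(replicate(40, sample(rownames(m)[hubs], 2))))
  pos <- pos[!duplicated(pair_keys_of(pos)), ]

  sw <- ratio_sweep(tab, pos, classifier_spec("categorical_nb"),
                    strategy = "N2", universe = rownames(m),
                    ratios = c(1, 3), selector = "ellipse", n_features = 10,
                    seed = 8)
  expect_named(sw, c("1:1", "1:3"))
  n_pos <- nrow(pos)
  expect_equal(sw[["1:1"]]$n_train + sw[["1:1"]]$n_test, 2 * n_pos)
  expect_equal(sw[["1:3"]]$n_train + sw[["1:3"]]$n_test, 4 * n_pos)
  m11 <- sw[["1:1"]]$metrics
  expect_gt(m11$accuracy, 0.5)
  expect_gt(sw[["1:1"]]$roc$auc, 0.5)
})

test_that("without signal, accuracy tracks the majority class as the ratio grows", {
  set.seed(62)
  m <- matrix(rbinom(60 * 30, 1, 0.2), 60, 30,
              dimnames = list(sprintf("D%02d", 1:60), NULL))
  tab <- drug_feature_table(m, "target")
  pos <- as_drug_pairs(t(replicate(40, sample(rownames(m), 2))))
  pos <- pos[!duplicated(pair_keys_of(pos)), ]
  sw <- ratio_sweep(tab, pos, classifier_spec("improved_nb"),
                    strategy = "N2", universe = rownames(m), ratios = 3,
                    selector = "ellipse", n_features = 10, seed = 9)
  m13 <- sw[["1:3"]]$metrics
  # majority (non-effective) prediction dominates: accuracy near 0.75,
  # recall of the minority effective class poor
  expect_gt(m13$accuracy, 0.55)
  expect_lt(m13$recall, 0.6)
})

test_that("y-randomization preserves class counts and passes the identity check", {
  set.seed(71)
  X <- matrix(rbinom(40 * 8, 1, 0.4), 40)
  y <- rep(c(0L, 1L), 20)
  yr <- y_randomization(classifier_spec("categorical_nb"), X, y,
                        selector = "none", n_shuffles = 2, seed = 5)
  for (s in yr$shuffled) expect_equal(sum(s$y), sum(y))

  # identity permutation reproduces the original performance exactly
  yr_id <- y_randomization(classifier_spec("categorical_nb"), X, y,
                           selector = "none",
                           permutations = list(seq_along(y)))
  expect_equal(yr_id$shuffled_auc, yr_id$original_auc)
  expect_equal(yr_id$shuffled[[1]]$scores, yr_id$original$scores)
})

test_that("confusion recovery inverts rounded metrics exhaustively", {
  # unique recovery of the published 1:1 side-effect row
  hits <- recover_confusion_from_metrics(0.6800, 0.6400, 0.6957,
                                         n_range = 48:52)
  expect_length(hits, 1)
  expect_equal(unclass(hits[[1]])[c("TP", "FP", "FN", "TN")],
               list(TP = 16L, FP = 7L, FN = 9L, TN = 18L))

  # a larger instance: the target-feature independent test
  hits2 <- recover_confusion_from_metrics(0.7034, 0.5000, 0.9008,
                                          n_range = 400:416)
  expect_length(hits2, 1)
  expect_equal(unclass(hits2[[1]])[c("TP", "FP", "FN", "TN")],
               list(TP = 109L, FP = 12L, FN = 109L, TN = 178L))

  # perfect metrics admit only error-free matrices
  hits3 <- recover_confusion_from_metrics(1, 1, 1, n_range = 2:4)
  expect_true(all(vapply(hits3, function(h) h$FP + h$FN == 0, logical(1))))

  expect_error(recover_confusion_from_metrics(0.123, 0.9, 0.1, 3:4),
               "no integer confusion matrix")
})
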