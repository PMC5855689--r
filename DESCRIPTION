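Package: combiNB
Title: Predicting Effective Drug Combinations with a Correlation-Aware
    Naive Bayes Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting effective two-drug combinations from
    sparse per-drug annotation profiles (targets, pathways, metabolic
    enzymes, transporters, dose-coded side effects).  Drug pairs are
    encoded by elementwise summation of the two drugs' feature vectors,
    screened with an ellipse-based frequency-shift statistic, and
    classified with an improved naive Bayes model that whitens the
    features in the eigenbasis of their correlation matrix, estimated
    from labeled and unlabeled samples together.  Includes conventional
    baseline classifiers (categorical naive Bayes, k-nearest neighbours,
    RBF support vector machine), leave-one-out cross-validation with
    in-fold feature selection, train/test splitting, negative-sampling
    strategies and ratio sweeps, y-randomization validation, ROC/AUC and
    confusion-matrix metrics, and a seeded synthetic-data generator that
    emulates the sparse correlated structure of real drug feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
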