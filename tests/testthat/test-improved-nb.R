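# helper: a pass-through "transform" (linear identity on [-100, 100]) so
# score formulas can be checked against hand arithmetic
identity_transform <- function(p) {
  m <- list(value = c(-100, 100), score = c(-100, 100))
  structure(list(maps = rep(list(m), p), n = 100,
                 constant = rep(FALSE, p), colnames = NULL),
            class = "normal_transform")
}

manual_model <- function(r, priors = c("0" = 0.5, "1" = 0.5),
                         class_means = rbind("0" = c(0, 0), "1" = c(0, 0)),
                         class_sds = rbind("0" = c(1, 1), "1" = c(1, 1))) {
  R <- matrix(c(1, r, r, 1), 2)
  structure(list(transform = identity_transform(2), R = R,
                 lambda = c(1 + r, 1 - r),
                 P = cbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2)),
                 class_means = class_means, class_sds = class_sds,
                 overall_means = c(0, 0), overall_sds = c(1, 1),
                 priors = priors, n_labeled = 4L, n_unlabeled = 0L,
                 correlation = TRUE, lambda_floor = 1e-6, sigma_floor = 1e-6,
                 train_X = matrix(0, 4, 2), train_y = c(0L, 0L, 1L, 1L),
                 feature_names = NULL),
            class = "improved_nb")
}

test_that("fitting recovers the correlation eigenstructure analytically", {
  set.seed(14)
  n <- 400
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n, sd = 0.8), b = z + rnorm(n, sd = 0.8))
  y <- rep(c(0L, 1L), n / 2)
  fit <- improved_nb(X, y)

  Z <- predict(fit$transform, X)
  r_emp <- cor(Z)[1, 2]
  expect_equal(fit$R[1, 2], r_emp, tolerance = 1e-12)
  expect_gt(r_emp, 0.4)

  # 2x2 eigendecomposition: lambda = 1 +/- r, eigenvectors (1,1)/sqrt(2)
  # and (1,-1)/sqrt(2) up to sign
  expect_equal(sort(fit$lambda), sort(c(1 + r_emp, 1 - r_emp)),
               tolerance = 1e-10)
  expect_equal(abs(fit$P), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-10)
})

test_that("every fit yields a valid whitened basis and moment set", {
  set.seed(2)
  for (i in 1:8) {
    p <- sample(2:6, 1); n <- sample(20:60, 1)
    X <- matrix(rpois(n * p, 2), n, p)
    y <- c(0L, 0L, 1L, 1L, sample(0:1, n - 4, replace = TRUE))
    fit <- improved_nb(X, y)
    expect_equal(sum(fit$lambda), p, tolerance = 1e-8)
    expect_lt(max(abs(crossprod(fit$P) - diag(p))), 1e-8)
    expect_true(all(fit$lambda >= 0))
    expect_true(all(fit$class_sds > 0) && all(fit$overall_sds > 0))
    expect_true(all(abs(fit$R[!diag(p)]) <= 1 + 1e-12))
    expect_equal(unname(diag(fit$R)), rep(1, p))
    expect_equal(sum(fit$priors), 1)
  }
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(improved_nb(X, c(1L, 0L, 0L, 0L, 0L, 0L)), "at least 2")
  expect_error(improved_nb(X[0, ], integer(0)), "empty|at least")
  expect_error(improved_nb(X, c(2, 0, 0, 1, 1, 1)), "0/1")
})

test_that("score formulas match hand arithmetic in the analytic eigenbasis", {
  m <- manual_model(r = 0.5)
  sc <- score_samples(m, matrix(c(1, 1), 1))
  expect_equal(unname(sc$beta[1, ]), c(sqrt(2), 0), tolerance = 1e-12)
  expect_equal(unname(sc$gamma_by_class[["1"]][1, ]), c(sqrt(2), 0),
               tolerance = 1e-12)
  # beta == gamma -> L = 0 for both classes
  expect_equal(unname(sc$L[1, ]), c(0, 0), tolerance = 1e-12)
  # H_k = ln 0.5 - (gamma_1^2 / (2 * 1.5) + 0) = ln 0.5 - 2/3
  expect_equal(unname(sc$H[1, ]), rep(log(0.5) - 2 / 3, 2),
               tolerance = 1e-12)
})

test_that("a sample at a class mean maximizes that class's H", {
  cm <- rbind("0" = c(-1, -1), "1" = c(1, 1))
  m <- manual_model(r = 0.3, class_means = cm)
  sc <- score_samples(m, rbind(c(1, 1), c(-1, -1)))
  # gamma vanishes for the matching class, so H reduces to its maximum
  expect_equal(unname(sc$gamma_by_class[["1"]][1, ]), c(0, 0))
  expect_gt(sc$H[1, "1"], sc$H[1, "0"])
  expect_gt(sc$H[2, "0"], sc$H[2, "1"])
  expect_equal(predict(m, rbind(c(1, 1), c(-1, -1)), type = "class"),
               c(1L, 0L))
})

test_that("priors dominate and exact ties fall to non-effective", {
  cm <- rbind("0" = c(-0.1, -0.1), "1" = c(0.1, 0.1))
  # extreme prior overwhelms a bounded class-mean advantage
  m_ext <- manual_model(r = 0, priors = c("0" = 1e-9, "1" = 1 - 1e-9),
                        class_means = cm)
  expect_equal(predict(m_ext, rbind(c(-0.4, -0.4)), type = "class"), 1L)

  # symmetric classes (independent features), sample equidistant from both
  # means: H tie -> 0
  m_sym <- manual_model(r = 0, priors = c("0" = 0.5, "1" = 0.5),
                        class_means = rbind("0" = c(-1, 0), "1" = c(1, 0)))
  sc <- score_samples(m_sym, rbind(c(0, 0.7)))
  expect_equal(unname(sc$H[1, "0"]), unname(sc$H[1, "1"]), tolerance = 1e-12)
  expect_equal(predict(m_sym, rbind(c(0, 0.7)), type = "class"), 0L)
})

test_that("feature order does not affect H and L", {
  set.seed(31)
  d <- generate_gaussian_study(n = 60, n_unlabeled = 0, n_features = 12,
                               block_size = 4, seed = 5)
  fit <- improved_nb(d$X, d$y)
  perm <- sample(12)
  fit_p <- improved_nb(d$X[, perm], d$y)
  Xn <- matrix(rnorm(10 * 12), 10)
  s1 <- score_samples(fit, Xn)
  s2 <- score_samples(fit_p, Xn[, perm])
  expect_equal(s1$H, s2$H, tolerance = 1e-10)
  expect_equal(s1$L, s2$L, tolerance = 1e-10)
})

test_that("JSON serialization round-trips scores to 1e-12", {
  d <- generate_gaussian_study(n = 60, n_unlabeled = 40, n_features = 12,
                               block_size = 4, seed = 17)
  fit <- improved_nb(d$X, d$y, unlabeled = d$unlabeled)
  path <- tempfile(fileext = ".json")
  write_improved_nb(fit, path)
  back <- read_improved_nb(path)
  Xn <- generate_gaussian_study(n = 30, n_unlabeled = 0, n_features = 12,
                                block_size = 4, seed = 18)$X
  s1 <- score_samples(fit, Xn); s2 <- score_samples(back, Xn)
  expect_lt(max(abs(s1$H - s2$H)), 1e-12)
  expect_lt(max(abs(s1$L - s2$L)), 1e-12)
  expect_equal(predict(fit, Xn, type = "class"),
               predict(back, Xn, type = "class"))
})

test_that("threshold rules behave on separated and shifted scores", {
  # perfectly separated calibration scores: chosen threshold classifies
  # the calibration set without error
  s <- c(rnorm(20, 10), rnorm(20, -10)); lab <- rep(c(1L, 0L), each = 20)
  th <- choose_threshold(s, lab)
  expect_true(all((s >= th) == (lab == 1L)))

  # translation equivariance of the decision rule
  expect_equal(choose_threshold(s + 3.7, lab), th + 3.7, tolerance = 1e-12)

  # closest-to-(0,1) alternative agrees here
  expect_equal(choose_threshold(s, lab, rule = "closest01"), th)

  expect_error(choose_threshold(s, rep(1L, 40)), "both classes")

  # end-to-end on a well-separated fit
  d <- generate_gaussian_study(n = 80, n_unlabeled = 0, n_features = 8,
                               block_size = 4, delta = 2.5, seed = 23)
  fit <- improved_nb(d$X, d$y)
  pr <- predict_by_threshold(fit, d$X)
  expect_gt(mean(pr$labels == d$y), 0.9)
})

test_that("class moments converge on the model's own generative data", {
  ref <- improved_nb(generate_gaussian_study(16000, 0, 12, 4, seed = 999)$X,
                     generate_gaussian_study(16000, 0, 12, 4, seed = 999)$y)
  truth_mu <- ref$class_means
  rmse <- function(n, s) {
    d <- generate_gaussian_study(n, 0, 12, 4, seed = s)
    fit <- improved_nb(d$X, d$y)
    sqrt(mean((fit$class_means - truth_mu)^2))
  }
  r_small <- vapply(1:20, function(s) rmse(100, s), numeric(1))
  r_large <- vapply(1:20, function(s) rmse(400, 100 + s), numeric(1))
  # root-n convergence: quadrupling n should about halve the error
  expect_lt(mean(r_large) / mean(r_small), 0.75)
})

test_that("an unlabeled pool sharpens the correlation estimate", {
  # population correlation of the class mixture (blocks of 4, rho, delta)
  p <- 12; bs <- 4; rho <- 0.5; delta <- 0.3
  block <- rep(1:(p / bs), each = bs)
  inf <- which(rep(1:bs, p / bs) == 1)
  mu <- numeric(p); mu[inf] <- delta
  Sigma <- outer(block, block, function(a, b) ifelse(a == b, rho, 0))
  diag(Sigma) <- 1
  Sigma <- Sigma + outer(mu, mu)          # between-class mean component
  R_pop <- cov2cor(Sigma)

  dist <- function(seed, with_pool) {
    d <- generate_gaussian_study(n = 60, n_unlabeled = 400, n_features = p,
                                 block_size = bs, rho = rho, delta = delta,
                                 seed = seed)
    fit <- improved_nb(d$X, d$y,
                       unlabeled = if (with_pool) d$unlabeled else NULL)
    sqrt(sum((fit$R - R_pop)^2))
  }
  d_no <- vapply(1:50, dist, numeric(1), with_pool = FALSE)
  d_yes <- vapply(1:50, dist, numeric(1), with_pool = TRUE)
  expect_lt(mean(d_yes), mean(d_no))
})

test_that("simulation reproduces the fitted moments and is seeded", {
  d <- generate_gaussian_study(n = 200, n_unlabeled = 0, n_features = 8,
                               block_size = 4, delta = 0.5, seed = 40)
  fit <- improved_nb(d$X, d$y)
  sim1 <- simulate(fit, nsim = 20000, seed = 7)
  sim2 <- simulate(fit, nsim = 20000, seed = 7)
  expect_identical(sim1$X, sim2$X)
  X1 <- sim1$X[sim1$y == 1, ]
  expect_lt(max(abs(colMeans(X1) - fit$class_means["1", ])), 0.05)
  # within a class the simulated correlation is the fitted R
  expect_lt(abs(cor(X1[, 1], X1[, 2]) - fit$R[1, 2]), 0.05)
})
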