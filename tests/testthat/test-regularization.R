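# Reduction (PCA / PLS-DA) and bagging regularized variants.

test_that("knee_point finds the elbow of a cumulative curve", {
  expect_equal(knee_point(c(0.5, 0.9, 0.95, 0.97, 0.99, 1.0)), 2L)
  expect_equal(knee_point(seq(0.2, 1, length.out = 5)), 1L)  # linear: no knee
})

test_that("elbow_components respects the data rank", {
  set.seed(1)
  base <- matrix(rnorm(40), 20, 2)
  x <- base %*% matrix(rnorm(20), 2, 10)       # rank-2 data in 10 dims
  expect_lte(elbow_components(x, max_components = 10), 2L)
  expect_error(elbow_components(matrix(1, 10, 4)), "degenerate")
})

test_that("PCA reduction to the full informative space reproduces naive (q=2)", {
  d <- make_blobs(20, 2, sep = 4, seed = 2)
  q <- matrix(rnorm(40), 20, 2)
  naive <- habic(d$x, d$y, q = 2, seed = 1)
  red <- habic(d$x, d$y, variant = "redPCA", n_components = 2, q = 2,
               seed = 1)
  # Euclidean ground metric is rotation invariant, so a full-rank PCA
  # projection must give the same predictions
  expect_equal(as.character(predict(red, q)), as.character(predict(naive, q)))
  expect_equal(red$w1, naive$w1, tolerance = 1e-8)
})

test_that("n_components is clipped to the rank bound with a warning", {
  d <- make_blobs(10, 3, seed = 3)
  expect_warning(fit <- habic(d$x, d$y, variant = "redPCA",
                              n_components = 50, seed = 1), "clipped")
  expect_lte(fit$reducer$n_components, 19L)
})

test_that("elbow delegation equals an explicit component count", {
  d <- make_blobs(15, 2, sep = 3, seed = 4, noise_p = 10)
  k <- elbow_components(d$x)
  f1 <- habic(d$x, d$y, variant = "redPCA", n_components = "elbow", seed = 5)
  f2 <- habic(d$x, d$y, variant = "redPCA", n_components = k, seed = 5)
  expect_equal(f1$reducer$n_components, k)
  expect_identical(f1$alpha, f2$alpha)
})

test_that("PCA reduction denoises: CV AUC at least matches naive on noisy data", {
  aucs <- sapply(1:5, function(s) {
    d <- make_blobs(15, 2, sep = 4, seed = 30 + s, noise_p = 50)
    c(red = habic_cv(d$x, d$y, k = 3, seed = s, variant = "redPCA",
                     n_components = 2)$auc_mean,
      naive = habic_cv(d$x, d$y, k = 3, seed = s)$auc_mean)
  })
  expect_gte(mean(aucs["red", ]), mean(aucs["naive", ]))
})

test_that("redPLS fits and predicts on separable data", {
  d <- make_blobs(15, 3, sep = 4, seed = 6, noise_p = 5)
  fit <- habic(d$x, d$y, variant = "redPLS", n_components = 2, seed = 1)
  expect_equal(mean(predict(fit, d$x) == d$y), 1.0)
})

test_that("PLS-DA importance singles out a perfect predictor", {
  set.seed(7)
  y <- rep(0:1, each = 20)
  x <- cbind(matrix(rnorm(40 * 6), 40, 6), y)  # label duplicated as feature 7
  imp <- plsda_importance(x, y)
  expect_equal(which.max(imp), 7L, ignore_attr = TRUE)
  # permuting feature order permutes importances identically
  ord <- c(4, 7, 1, 3, 6, 2, 5)
  imp_p <- plsda_importance(x[, ord], y)
  expect_equal(as.numeric(imp_p), as.numeric(imp[ord]), tolerance = 1e-10)
  # constant features get zero importance
  imp_c <- plsda_importance(cbind(x, 5), y)
  expect_equal(as.numeric(imp_c[8]), 0)
})

test_that("pure-noise features produce no dominant PLS-DA importance", {
  ratios <- sapply(1:5, function(s) {
    set.seed(40 + s)
    x <- matrix(rnorm(60 * 20), 60, 20)
    imp <- plsda_importance(x, rep(0:1, 30))
    max(imp) / median(imp)
  })
  expect_lt(mean(ratios), 10)
})

test_that("bagSTD with B = 1 and a full feature draw reduces to naive", {
  d <- make_blobs(12, 4, sep = 2, seed = 8)
  bag <- habic(d$x, d$y, variant = "bagSTD", B = 1, mtry = 4, seed = 21)
  mem <- bag$members[[1]]
  expect_equal(sort(mem$features), 1:4)
  ref <- habic(d$x[mem$rows, ], d$y[mem$rows], seed = 99)  # same bootstrap
  q <- matrix(rnorm(60), 15, 4)
  expect_equal(as.character(predict(bag, q)), as.character(predict(ref, q)))
  expect_identical(mem$fit$alpha, ref$alpha)
})

test_that("bagged ensembles classify separable blobs perfectly", {
  d <- make_blobs(20, 3, sep = 5, seed = 9, noise_p = 3)
  for (v in c("bagSTD", "bagRF", "bagPLS")) {
    fit <- habic(d$x, d$y, variant = v, B = 15, n_keep = 2, seed = 4)
    expect_equal(mean(predict(fit, d$x) == d$y), 1.0)
  }
})

test_that("ensemble predictions are invariant to member order", {
  d <- make_blobs(12, 5, sep = 1, seed = 10)
  fit <- habic(d$x, d$y, variant = "bagSTD", B = 9, seed = 2)
  rev_fit <- fit
  rev_fit$members <- rev(fit$members)
  q <- matrix(rnorm(50), 10, 5)
  expect_identical(predict(fit, q), predict(rev_fit, q))
  expect_equal(predict(fit, q, type = "margin"),
               predict(rev_fit, q, type = "margin"))
})

test_that("majority vote follows the votes, margins only break exact ties", {
  # construct a 2-member ensemble with opposing votes and a known margin
  d <- make_blobs(10, 2, sep = 3, seed = 11)
  fit <- habic(d$x, d$y, variant = "bagSTD", B = 2, mtry = 2, seed = 3)
  q <- matrix(rnorm(20, 0, 2), 10, 2)
  votes <- sapply(fit$members, function(mem) {
    f <- mem$fit
    g <- predict(f$optimizer, q[, mem$features, drop = FALSE])
    ifelse((g > f$alpha) == (f$high_class == "1"), "1", "0")
  })
  marg <- predict(fit, q, type = "margin")
  pred <- as.character(predict(fit, q))
  for (i in 1:10) {
    n1 <- sum(votes[i, ] == "1")
    expected <- if (n1 > 1) "1" else if (n1 < 1) "0"
                else if (marg[i] > 0) "1" else "0"
    expect_equal(pred[i], expected)
  }
})

test_that("PLS filtering concentrates members on the informative features", {
  set.seed(12)
  n <- 60
  y <- rep(0:1, each = n / 2)
  signal <- outer(2 * y - 1, c(1.5, -1.5, 1.5)) + matrix(rnorm(n * 3), n, 3)
  x <- cbind(signal, matrix(rnorm(n * 27), n, 27))
  fit <- habic(x, y, variant = "bagPLS", B = 30, mtry = 30, n_keep = 3,
               seed = 5)
  kept <- table(factor(unlist(lapply(fit$members, `[[`, "features")),
                       levels = 1:30))
  # every member drew all 30 features; the 3 informative ones must be kept
  # far more often than chance (3/30 of members each)
  expect_true(all(kept[1:3] > 15))
})

test_that("importance-fraction filtering keeps a minimal covering prefix", {
  d <- make_blobs(15, 3, sep = 3, seed = 13, noise_p = 7)
  fit <- habic(d$x, d$y, variant = "bagPLS", B = 5, mtry = 10,
               importance_fraction = 0.7, seed = 6)
  sizes <- lengths(lapply(fit$members, `[[`, "features"))
  expect_true(all(sizes >= 1 & sizes <= 10))
})
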