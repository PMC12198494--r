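# Exact transport core: cost matrices, assignment duals, KR optimizer.

test_that("Minkowski cost matrix matches the direct formula", {
  expect_equal(as.numeric(minkowski_cost(rbind(c(1, 2)), rbind(c(1, 2)), 1)),
               0)
  expect_equal(as.numeric(minkowski_cost(rbind(c(1, 2)), rbind(c(4, 6)), 2)),
               5)
  expect_equal(as.numeric(minkowski_cost(rbind(c(1, 2)), rbind(c(4, 6)), 1)),
               7)
  # sampled entries against the formula, several orders
  set.seed(1)
  x0 <- matrix(rnorm(15), 5, 3)
  x1 <- matrix(rnorm(12), 4, 3)
  for (q in c(1, 2, 5, 10)) {
    d <- minkowski_cost(x0, x1, q)
    for (k in 1:6) {
      i <- sample(5, 1); j <- sample(4, 1)
      expect_equal(d[i, j], sum(abs(x0[i, ] - x1[j, ])^q)^(1 / q))
    }
    expect_equal(unclass(d), t(minkowski_cost(x1, x0, q)),
                 ignore_attr = TRUE)
  }
})

test_that("cost matrix rejects bad input with informative errors", {
  expect_error(minkowski_cost(matrix(1, 2, 3), matrix(1, 2, 4)),
               "2 x 3.*2 x 4")
  expect_error(minkowski_cost(matrix(c(1, NA), 1), matrix(c(1, 2), 1)),
               "non-finite")
  expect_error(minkowski_cost(matrix(1), matrix(1), q = 0.5), "q")
})

test_that("assignment solve matches brute force and certifies duals", {
  p1 <- solve_assignment(matrix(0))
  expect_equal(p1$perm, 1L)
  expect_equal(p1$total_cost, 0)
  expect_equal(p1$psi + p1$phi, 0)

  pts <- matrix(rnorm(6), 3, 2)
  pid <- solve_assignment(minkowski_cost(pts, pts, 1))
  expect_equal(pid$total_cost, 0)
  expect_equal(pid$w1, 0)

  p2 <- solve_assignment(rbind(c(4, 1), c(2, 3)))
  expect_equal(p2$perm, c(2L, 1L))
  expect_equal(p2$total_cost, 3)

  set.seed(7)
  for (r in 1:200) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, 0, 10), n)
    plan <- solve_assignment(cost)
    expect_equal(plan$total_cost, brute_force_assignment(cost))
    expect_true(validate_transport_plan(plan, cost))
    expect_equal(plan$w1, plan$total_cost / n)
  }
})

test_that("assignment solve rejects non-square and NaN cost matrices", {
  expect_error(solve_assignment(matrix(1, 2, 3)), "balance")
  expect_error(solve_assignment(matrix(c(1, NaN, 2, 3), 2)), "NA")
})

test_that("degenerate 1-pair optimizer reproduces the hand-computed scores", {
  cost <- minkowski_cost(matrix(0), matrix(1), 1)
  plan <- solve_assignment(cost)
  g <- kr_optimizer(matrix(0), matrix(1), plan, 1)
  # duals for this instance are psi + phi = 1; scores are dual-valued
  expect_equal(predict(g, 0), plan$psi[1])
  expect_equal(predict(g, 1), -plan$phi[1])
  # averaged extension at the midpoint and in the far field
  expect_equal(predict(g, 0.5), 0.5)
  expect_equal(predict(g, 10), 0)
  comp <- predict(g, 0.5, type = "components")
  expect_equal(as.numeric(comp), c(0.5, 0.5))
  # both extensions agree with the potentials on the support
  expect_equal(as.numeric(predict(g, 0, type = "components")),
               rep(plan$psi[1], 2))
  expect_equal(as.numeric(predict(g, 1, type = "components")),
               rep(-plan$phi[1], 2))
})

test_that("optimizer scores are invariant to relabeling the input rows", {
  set.seed(2)
  x0 <- matrix(rnorm(20), 5, 4)
  x1 <- matrix(rnorm(20), 5, 4)
  g <- kr_optimizer(x0, x1, solve_assignment(minkowski_cost(x0, x1, 1)), 1)
  ord <- c(3, 1, 5, 2, 4)
  x0p <- x0[ord, ]
  x1p <- x1[ord, ]
  gp <- kr_optimizer(x0p, x1p,
                     solve_assignment(minkowski_cost(x0p, x1p, 1)), 1)
  queries <- matrix(rnorm(40), 10, 4)
  expect_equal(predict(g, queries), predict(gp, queries), tolerance = 1e-10)
})

test_that("empirical-mean identity: mean g(x0) - mean g(x1) equals W1", {
  set.seed(3)
  for (q in c(1, 2)) {
    x0 <- matrix(rnorm(30), 6, 5)
    x1 <- matrix(rnorm(30, 0.5), 6, 5)
    plan <- solve_assignment(minkowski_cost(x0, x1, q))
    g <- kr_optimizer(x0, x1, plan, q)
    expect_equal(mean(predict(g, x0)) - mean(predict(g, x1)), plan$w1)
  }
})

test_that("the averaged extension and both components are 1-Lipschitz", {
  set.seed(4)
  x0 <- matrix(rnorm(40), 8, 5)
  x1 <- matrix(rnorm(40, 1), 8, 5)
  for (q in c(1, 2)) {
    g <- kr_optimizer(x0, x1, solve_assignment(minkowski_cost(x0, x1, q)), q)
    s <- matrix(rnorm(1200 * 5, 0, 3), ncol = 5)
    t_ <- matrix(rnorm(1200 * 5, 0, 3), ncol = 5)
    dst <- rowSums(abs(s - t_)^q)^(1 / q)
    comp_s <- predict(g, s, type = "components")
    comp_t <- predict(g, t_, type = "components")
    gs <- rowMeans(comp_s)
    gt <- rowMeans(comp_t)
    tol <- 1e-10
    expect_true(all(abs(gs - gt) <= dst + tol))
    expect_true(all(abs(comp_s[, 1] - comp_t[, 1]) <= dst + tol))
    expect_true(all(abs(comp_s[, 2] - comp_t[, 2]) <= dst + tol))
  }
})

test_that("W1 is translation invariant and positively homogeneous", {
  set.seed(5)
  x0 <- matrix(rnorm(24), 6, 4)
  x1 <- matrix(rnorm(24, 1), 6, 4)
  w <- solve_assignment(minkowski_cost(x0, x1, 1))$w1
  shift <- matrix(rnorm(4, 10), 6, 4, byrow = TRUE)
  w_sh <- solve_assignment(minkowski_cost(x0 + shift, x1 + shift, 1))$w1
  expect_equal(w_sh, w)
  lam <- 2.7
  w_sc <- solve_assignment(minkowski_cost(lam * x0, lam * x1, 1))$w1
  expect_equal(w_sc, lam * w)
  # score differences are translation invariant too
  g <- kr_optimizer(x0, x1, solve_assignment(minkowski_cost(x0, x1, 1)), 1)
  gsh <- kr_optimizer(x0 + shift, x1 + shift,
                      solve_assignment(minkowski_cost(x0 + shift,
                                                      x1 + shift, 1)), 1)
  qr1 <- matrix(rnorm(20), 5, 4)
  d1 <- diff(predict(g, qr1))
  d2 <- diff(predict(gsh, sweep(qr1, 2, shift[1, ], "+")))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("W1 between same-distribution samples shrinks as n grows", {
  w_at_n <- function(n, seed) {
    set.seed(seed)
    x0 <- matrix(rnorm(n * 3), n, 3)
    x1 <- matrix(rnorm(n * 3), n, 3)
    solve_assignment(minkowski_cost(x0, x1, 1))$w1
  }
  w <- sapply(c(25, 100, 400), function(n)
    mean(sapply(1:4, function(s) w_at_n(n, 100 + s))))
  expect_true(w[1] > w[2])
  expect_true(w[2] > w[3])
})

test_that("transport plan TSV export has the documented columns", {
  plan <- solve_assignment(minkowski_cost(matrix(rnorm(8), 4, 2),
                                          matrix(rnorm(8), 4, 2), 1))
  f <- tempfile(fileext = ".tsv")
  write_plan_tsv(plan, f)
  d <- read.delim(f)
  expect_named(d, c("i", "pi_i", "psi_i", "phi_pi_i", "cost_i"))
  expect_equal(d$pi_i, plan$perm)
  expect_equal(d$psi_i + d$phi_pi_i, d$cost_i, tolerance = 1e-10)
})
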