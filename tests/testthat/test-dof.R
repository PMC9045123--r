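test_that("svd_decompose recovers singular values and reconstructs the input", {
  x <- delta_matrix(diag(c(3, 2, 1)), centered = TRUE)
  b <- svd_decompose(x)
  expect_equal(b$sigma, c(3, 2, 1))
  # rank-2 noiseless world: exactly 2 values above threshold
  w <- make_world(rank = 2, seed = 2)
  b2 <- svd_decompose(center_and_impute(w$delta))
  expect_equal(sum(b2$sigma > 1e-10 * b2$sigma[1]), 2)
  # reconstruction against a direct matrix-multiply oracle
  set.seed(8)
  v <- matrix(rnorm(200), 20, 10)
  b3 <- svd_decompose(delta_matrix(v, centered = TRUE))
  rec <- b3$U %*% diag(b3$sigma) %*% t(b3$V)
  expect_lt(norm(rec - v, "F") / norm(v, "F"), 1e-10)
  expect_lt(max(abs(crossprod(b3$U) - diag(10))), 1e-8)
  expect_lt(max(abs(crossprod(b3$V) - diag(10))), 1e-8)
})

test_that("svd sign convention makes the factorisation deterministic", {
  set.seed(9)
  v <- matrix(rnorm(300), 30, 10)
  b1 <- svd_decompose(delta_matrix(v, centered = TRUE))
  b2 <- svd_decompose(delta_matrix(v[, ], centered = TRUE))
  expect_identical(b1$U, b2$U)
  for (j in seq_len(ncol(b1$U)))
    expect_gt(b1$U[which.max(abs(b1$U[, j])), j], 0)
})

test_that("cv_error matches the explicit-loop oracle on small instances", {
  set.seed(12)
  for (i in 1:5) {
    n <- sample(2:5, 1); E <- sample(2:5, 1); k <- sample(0:(E - 1), 1)
    tb <- matrix(rnorm(n * E), n, E)
    P <- if (k == 0) NULL else qr.Q(qr(matrix(rnorm(E * k), E, k)))
    expect_equal(cv_error(tb, P), oracle_cv_error(tb, P), tolerance = 1e-12)
  }
})

test_that("cv_error equals the squared Frobenius norm at both endpoints", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:8, 1); E <- sample(3:10, 1)
    tb <- matrix(rnorm(n * E), n, E)
    fro2 <- sum(tb^2)
    expect_equal(cv_error(tb, NULL), fro2, tolerance = 1e-10)
    P_full <- qr.Q(qr(matrix(rnorm(E * E), E, E)))
    expect_equal(cv_error(tb, P_full), fro2, tolerance = 1e-10 * fro2)
  }
})

test_that("cv_error validates the experiment axis", {
  expect_error(cv_error(matrix(0, 2, 3), matrix(0, 4, 1)), "column count")
})

test_that("golden-section search finds integer unimodal minima", {
  expect_equal(as.integer(golden_section_min(function(k) (k - 7)^2, 1, 100)), 7L)
  expect_equal(as.integer(golden_section_min(function(k) k, 1, 50)), 1L)
  expect_equal(as.integer(golden_section_min(function(k) -k, 1, 50)), 50L)
  # matches exhaustive scan on random convex integer quadratics
  set.seed(13)
  for (i in 1:100) {
    vertex <- runif(1, -20, 120)
    a <- runif(1, 0.1, 5)
    f <- function(k) a * (k - vertex)^2
    lo <- 1L; hi <- 100L
    got <- as.integer(golden_section_min(f, lo, hi))
    scan <- lo:hi
    want <- scan[which.min(f(scan))]
    expect_identical(got, want)
  }
})

test_that("golden-section memoizes and reports its evaluation trace", {
  calls <- 0L
  f <- function(k) { calls <<- calls + 1L; (k - 30)^2 }
  res <- golden_section_min(f, 1, 200)
  ev <- attr(res, "evaluations")
  expect_identical(calls, nrow(ev))      # every evaluation was fresh
  expect_lt(nrow(ev), 40)                # far fewer than the 200-point scan
})

test_that("estimate_dof recovers the planted rank on synthetic data", {
  truth <- synthetic_truth(rank = 8, singular_values = seq(40, 15, length.out = 8),
                           noise_sd = 0.1, seed = 17)
  sim <- simulate_low_rank_delta(600, 150, truth)
  fit <- estimate_dof(sim$delta, n_train = 480, n_repeats = 5, seed = 17,
                      bracket = c(1, 75))
  expect_lte(abs(fit$mean - 8), 2)
  expect_equal(fit$n_repeats, 5)
  expect_equal(length(fit$runs), 5)
  expect_equal(fit$mean, mean(fit$runs))
  expect_equal(fit$min, min(fit$runs))
})

test_that("pure-noise data selects a near-zero dimension", {
  set.seed(19)
  v <- matrix(rnorm(400 * 80), 400, 80)
  x <- delta_matrix(v)
  fit <- estimate_dof(x, n_train = 320, n_repeats = 15, seed = 19,
                      bracket = c(1, 40))
  expect_gte(sum(fit$runs <= 5), 13)
})

test_that("estimate_dof is invariant to gene ordering given the same splits", {
  w <- make_world(n_genes = 150, n_experiments = 40, rank = 3,
                  noise_sd = 0.05, seed = 23)
  fit1 <- estimate_dof(w$delta, n_train = 120, n_repeats = 3, seed = 23,
                       bracket = c(1, 20))
  perm <- sample(150)
  x2 <- delta_matrix(w$delta$values[perm, ], gene_ids = w$delta$gene_ids[perm])
  fit2 <- estimate_dof(x2, n_train = 120, n_repeats = 3, seed = 23,
                       bracket = c(1, 20))
  # split membership differs only through row labels; the selected
  # dimension distribution must not depend on gene order
  expect_identical(sort(fit1$runs), sort(fit2$runs))
})

test_that("estimate_dof validates its preconditions", {
  w <- make_world(n_genes = 30, n_experiments = 10, rank = 2, seed = 29)
  expect_error(estimate_dof(w$delta, n_train = 30), "smaller")
  one_col <- delta_matrix(matrix(rnorm(30), 30, 1))
  expect_error(estimate_dof(one_col, n_train = 20), "2 experiments")
})

test_that("dof_vs_datasize tracks resolvable rank and reports increments", {
  # true rank above every tested size's resolvable rank: mean DOF should
  # be non-decreasing in the number of experiments
  truth <- synthetic_truth(rank = 30, singular_values = seq(60, 20, length.out = 30),
                           noise_sd = 0.1, seed = 31)
  sim <- simulate_low_rank_delta(260, 36, truth)
  curve <- dof_vs_datasize(sim$delta, sizes = c(12, 24, 36),
                           axis = "experiments", n_repeats = 3,
                           n_train = 200, seed = 31, bracket = c(1, 34))
  expect_true(all(diff(curve$mean_dof) >= 0))
  inc <- attr(curve, "increments")
  expect_equal(nrow(inc), 2)
  expect_equal(inc$increment, diff(curve$mean_dof))
  expect_error(dof_vs_datasize(sim$delta, sizes = 50, axis = "experiments",
                               n_repeats = 1, seed = 1), "exceeds")
})

test_that("gene-size sweep leaves the DOF estimate flat at fixed rank", {
  truth <- synthetic_truth(rank = 5, singular_values = seq(35, 15, length.out = 5),
                           noise_sd = 0.1, seed = 37)
  sim <- simulate_low_rank_delta(500, 80, truth)
  curve <- dof_vs_datasize(sim$delta, sizes = c(250, 375, 500), axis = "genes",
                           n_repeats = 3, n_train = 400, seed = 37,
                           bracket = c(1, 40))
  expect_true(all(abs(curve$mean_dof - 5) <= 2))
})

test_that("quadratic and linear extrapolations are exact on analytic inputs", {
  x <- c(1, 3, 6, 9, 11)
  y <- -(x - 11)^2 + 443
  q <- extrapolate_quadric(x, y)
  expect_equal(q$vertex_size, 11, tolerance = 1e-8)
  expect_equal(q$vertex_dof, 443, tolerance = 1e-8)
  # increments declining linearly from 72 at x = 1.5, slope -8
  xs <- c(1.5, 2.5, 3.5, 4.5)
  inc <- 72 - 8 * (xs - 1.5)
  l <- extrapolate_linear_increments(xs, inc)
  expect_equal(l$zero_crossing_size, 1.5 + 72 / 8, tolerance = 1e-8)
  # a convex parabola has no maximum
  expect_error(extrapolate_quadric(x, (x - 2)^2), "maximum")
  expect_error(extrapolate_quadric(c(1, 1, 1), c(1, 2, 3)), "collinear|degenerate")
})
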