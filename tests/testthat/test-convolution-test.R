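test_that("bin_mdd uses the fixed 11-bin lattice with singleton integers", {
  b <- bin_mdd(c(3.0, 3.5, 8.2))
  expect_identical(b$labels[b$counts > 0], c("{3}", "(3,4)", "[7,Inf)"))
  expect_identical(b$labels, c("{2}", "(2,3)", "{3}", "(3,4)", "{4}",
                               "(4,5)", "{5}", "(5,6)", "{6}", "(6,7)",
                               "[7,Inf)"))
  expect_identical(which(bin_mdd(2)$counts > 0), 1L)       # {2}
  expect_identical(which(bin_mdd(7)$counts > 0), 11L)      # [7, Inf)
  expect_identical(which(bin_mdd(6.5)$counts > 0), 10L)    # (6, 7)
  expect_warning(bu <- bin_mdd(c(1.5, 3)), "underflow")
  expect_identical(bu$labels[1], "(-Inf,2)")
  expect_identical(length(bu$counts), 12L)
})

test_that("sparse-category projection merges adjacent bins identically", {
  p1 <- c(0.05, 0.4, 0.4, 0.15); p2 <- c(0.1, 0.35, 0.4, 0.15)
  expect_identical(project_to_common_categories(p1, p2, 100, min_count = 0),
                   diag(4))
  P <- project_to_common_categories(c(0.5, 0.5, 0), c(0.45, 0.55, 0),
                                    n_eff = 100, min_count = 5)
  expect_identical(nrow(P), 2L)
  expect_true(all(colSums(P) == 1))    # every category lands in one group
  expect_error(project_to_common_categories(c(1), c(1), 10, 5), "incompatible|categories")
})

test_that("identical inputs give S = 0, p = 1", {
  X <- c(10, 20, 15); Y <- c(12, 18)
  res <- convolution_equality_test(X, Y, X, Y)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})

test_that("degenerate single-category inputs yield rank 0 with a warning", {
  expect_warning(
    res <- convolution_equality_test(c(30, 0), c(25, 0), c(30, 0), c(25, 0),
                                     min_count = 0),
    "rank 0")
  expect_equal(res$p.value, 1)
})

test_that("incompatible convolved supports are rejected", {
  expect_error(convolution_equality_test(c(5, 5), c(5, 5), c(5, 5, 5), c(5, 5)),
               "incompatible")
})

test_that("the test is calibrated under H0 at moderate sample size", {
  set.seed(61)
  x <- c(0.2, 0.4, 0.3, 0.1); y <- c(0.3, 0.4, 0.3)
  pv <- replicate(500, {
    X <- rmultinom(1, 150, x)[, 1]; Y <- rmultinom(1, 150, y)[, 1]
    A <- rmultinom(1, 150, x)[, 1]; B <- rmultinom(1, 150, y)[, 1]
    convolution_equality_test(X, Y, A, B)$p.value
  })
  expect_gte(mean(pv < 0.05), 0.02)
  expect_lte(mean(pv < 0.05), 0.09)
})

test_that("the test has power against a one-category shift", {
  set.seed(62)
  x <- c(0.2, 0.4, 0.3, 0.1); y <- c(0.3, 0.4, 0.3)
  xs <- c(0, x[1:2], x[3] + x[4])   # distribution shifted by one category
  rej <- mean(replicate(120, {
    X <- rmultinom(1, 300, x)[, 1]; Y <- rmultinom(1, 300, y)[, 1]
    A <- rmultinom(1, 300, xs)[, 1]; B <- rmultinom(1, 300, y)[, 1]
    convolution_equality_test(X, Y, A, B)$p.value < 0.05
  }))
  expect_gt(rej, 0.8)
})

test_that("power is non-decreasing in sample size for a fixed alternative", {
  set.seed(63)
  x <- c(0.25, 0.45, 0.3); y <- c(0.4, 0.6)
  xa <- c(0.38, 0.42, 0.2)
  pow <- vapply(c(50, 100, 200, 400), function(n) {
    mean(replicate(150, {
      X <- rmultinom(1, n, x)[, 1]; Y <- rmultinom(1, n, y)[, 1]
      A <- rmultinom(1, n, xa)[, 1]; B <- rmultinom(1, n, y)[, 1]
      convolution_equality_test(X, Y, A, B)$p.value < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(pow) >= -0.08))   # monotone up to Monte-Carlo noise
  expect_gt(pow[4], pow[1])
})

test_that("assembled covariance matches the empirical covariance of V", {
  set.seed(64)
  x <- c(0.2, 0.4, 0.3, 0.1); y <- c(0.3, 0.4, 0.3)
  n <- 300; N <- 3000
  conv <- clonedd:::conv_probs
  Vs <- replicate(N, {
    X <- rmultinom(1, n, x)[, 1] / n; Y <- rmultinom(1, n, y)[, 1] / n
    A <- rmultinom(1, n, x)[, 1] / n; B <- rmultinom(1, n, y)[, 1] / n
    sqrt(n) * (conv(X, Y) - conv(A, B))
  })
  emp <- cov(t(Vs))
  J <- clonedd:::conv_jacobian
  mc <- function(p) diag(p) - tcrossprod(p)
  Sig <- 2 * (J(y, 4) %*% mc(x) %*% t(J(y, 4)) +
                J(x, 3) %*% mc(y) %*% t(J(x, 3)))
  se <- sqrt((outer(diag(Sig), diag(Sig)) + Sig^2) / N)
  expect_true(all(abs(emp - Sig) <= 5 * se + 2e-3))
})
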