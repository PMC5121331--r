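test_that("estimate_progression reconstructs cohort-corrected tail ratios", {
  expect_equal(estimate_progression(c(0, 0, 8))$p, c(1, 1, 0))
  expect_equal(estimate_progression(c(1, 0), max_depth = 1)$p, c(0, 0))
  prof <- estimate_progression(c(0, 1, 2))
  expect_equal(prof$p[2], 0.5)   # (2/4) / (1/2 + 2/4)
  expect_equal(prof$p, c(1, 0.5, 0))
  expect_error(estimate_progression(c(0, 0)), "positive")
})

test_that("enumerate_full_trees produces exactly the valid DD-count vectors", {
  expect_equal(unname(enumerate_full_trees(0)[, 1]), 1)
  d1 <- enumerate_full_trees(1)
  expect_identical(nrow(d1), 2L)
  expect_setequal(apply(d1, 1, paste, collapse = ","), c("1,0", "0,2"))
  d2 <- enumerate_full_trees(2)
  expect_identical(nrow(d2), 4L)
  expect_setequal(apply(d2, 1, paste, collapse = ","),
                  c("1,0,0", "0,2,0", "0,1,2", "0,0,4"))
  expect_identical(vapply(3:5, function(D) nrow(enumerate_full_trees(D)),
                          integer(1)), c(10L, 36L, 202L))
  expect_error(enumerate_full_trees(9), "depth")
  # structural invariants: t_i <= c_i, termination, exact cohort mass
  for (D in 0:5) {
    tr <- enumerate_full_trees(D)
    cells <- attr(tr, "cells")
    expect_true(all(tr <= cells))
    expect_true(all(apply(tr, 1, cohort_mass_is_one)))
    expect_false(anyDuplicated(tr) > 0)
  }
})

test_that("full-tree likelihoods match hand products and sum to 1", {
  prof0 <- dd_profile(0)
  expect_equal(full_tree_likelihood(c(1), dd_model(prof0, 0.3)), 1)
  expect_equal(full_tree_likelihood(c(0, 2), dd_model(dd_profile(c(1, 0)), 0.7)), 1)
  m <- dd_model(dd_profile(c(0.5, 0.5, 0)), 0)
  expect_equal(full_tree_likelihood(c(0, 1, 2), m), 0.25)
  expect_error(full_tree_likelihood(c(0, 1), m), "depth")
  expect_error(full_tree_likelihood(c(0, 2, 1), m), "terminate")
  set.seed(41)
  for (i in 1:5) {
    D <- sample(1:5, 1)
    prof <- dd_profile(c(runif(D), 0))
    mod <- dd_model(prof, runif(1))
    tot <- sum(apply(enumerate_full_trees(D), 1, full_tree_likelihood, model = mod))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("subtree sampling likelihood is per-generation binomial thinning", {
  expect_equal(subtree_sampling_likelihood(c(0, 2), c(0, 2), 1), 1)
  expect_equal(subtree_sampling_likelihood(c(0, 1), c(0, 2), 0.5), 0.5)
  expect_equal(subtree_sampling_likelihood(c(0, 0, 0), c(0, 0, 4), 0.5), 0.0625)
  expect_error(subtree_sampling_likelihood(c(0, 3), c(0, 2), 0.5), "exceed")
})

test_that("range distribution: degenerate cases and hand-computed mass", {
  # fully correlated families are perfectly concordant
  m1 <- dd_model(dd_profile(c(0.6, 0.3, 0)), rho = 1, r = 1)
  rd1 <- range_distribution(m1)
  expect_equal(rd1$prob[rd1$range == 0], 1)
  # depth-1 trees are single-generation whatever happens
  rd2 <- range_distribution(dd_model(dd_profile(c(0.5, 0)), 0, 1))
  expect_equal(rd2$prob[rd2$range == 0], 1)
  # only tree (0,1,2) has range 1 at D=2, r=1
  rd3 <- range_distribution(dd_model(dd_profile(c(0.5, 0.5, 0)), 0, 1))
  expect_equal(rd3$prob[rd3$range == 1], 0.25)
  expect_equal(sum(rd3$prob), 1, tolerance = 1e-12)
})

test_that("range distribution matches the Monte-Carlo oracle under sampling", {
  set.seed(42)
  prof <- dd_profile(c(0.8, 0.6, 0.5, 0))
  for (rho in c(0, 0.6)) for (r in c(0.5, 1)) {
    mod <- dd_model(prof, rho, r)
    ana <- range_distribution(mod)$prob
    tr <- simulate_full_trees(30000, prof, rho)
    s <- thin_trees(tr, r, drop_empty = TRUE)
    emp <- tabulate(row_ranges(s) + 1L, nbins = 4) / nrow(s)
    se <- sqrt(ana * (1 - ana) / nrow(s))
    expect_true(all(abs(emp - ana) <= 3 * se + 1e-12),
                info = sprintf("rho=%g r=%g", rho, r))
  }
})

test_that("concordance probability P(range=0) is non-decreasing in rho", {
  prof <- dd_profile(c(0.8, 0.7, 0.5, 0))
  p0 <- vapply(seq(0, 1, 0.1), function(rho)
    range_distribution(dd_model(prof, rho, 0.6))$prob[1], numeric(1))
  expect_true(all(diff(p0) >= -1e-12))
})

test_that("finite-sample range CIs are binomial envelopes", {
  rd <- data.frame(range = 0, prob = 1)
  class(rd) <- c("range_distribution", "data.frame")
  ci <- range_distribution_ci(rd, 50)
  expect_equal(ci$lower, 1); expect_equal(ci$upper, 1)
  rd2 <- data.frame(range = 0:1, prob = c(0.5, 0.5))
  class(rd2) <- c("range_distribution", "data.frame")
  ci2 <- range_distribution_ci(rd2, 100)
  expect_equal(ci2$lower[1], qbinom(0.025, 100, 0.5) / 100)
  expect_true(abs(ci2$lower[1] - 0.40) < 0.02)
  expect_true(abs(ci2$upper[1] - 0.60) < 0.02)
  ci3 <- range_distribution_ci(rd2, 1)
  expect_true(all(ci3$lower %in% c(0, 1)) && all(ci3$upper %in% c(0, 1)))
})

test_that("fit_rho finds the boundary for perfectly concordant data", {
  set.seed(43)
  prof <- dd_profile(c(0.8, 0.6, 0.4, 0))
  s <- simulate_full_trees(100, prof, rho = 1)   # r = 1: fully observed
  fit <- fit_rho(s, prof, r = 1)
  expect_identical(fit$rho, 1)
})

test_that("fit_rho recovers near-zero correlation from independent families", {
  set.seed(44)
  prof <- dd_profile(c(0.85, 0.7, 0.55, 0.3, 0))   # D = 4
  s <- simulate_full_trees(500, prof, rho = 0)
  fit <- fit_rho(s, prof, r = 1)
  expect_lt(fit$rho, 0.2)
  expect_equal(nrow(fit$grid), 101L)
})

test_that("fit_rho brackets strong correlation under heavy subsampling", {
  set.seed(45)
  prof <- dd_profile(c(0.85, 0.7, 0.55, 0.3, 0))
  tr <- simulate_full_trees(200, prof, rho = 0.9)
  s <- thin_trees(tr, 0.5)
  fit <- fit_rho(s, prof, r = 0.5)
  expect_gte(fit$rho, 0.75)
  expect_lte(fit$rho, 1)
})

test_that("pooled progression is rho-invariant and recovered in expectation", {
  set.seed(46)
  pi_in <- c(0.2, 0.35, 0.3, 0.15)
  prof <- profile_from_dd_distribution(pi_in, 1:4)
  for (rho in c(0, 0.9)) {
    tr <- simulate_full_trees(100000, prof, rho)
    pooled <- colSums(tr)
    q <- cohort_normalize(pooled)
    expect_equal(q, c(0, pi_in), tolerance = 0.02)
  }
})
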