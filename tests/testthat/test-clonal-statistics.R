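test_that("clone_range is max minus min generation, order-invariant", {
  expect_identical(clone_range(c(3, 3, 3)), 0L)
  expect_identical(clone_range(c(4, 5)), 1L)
  expect_identical(clone_range(c(2, 4, 7)), 5L)
  expect_error(clone_range(integer(0)), "no detected progeny")
  set.seed(21)
  for (i in 1:20) {
    g <- sample(0:7, sample(1:6, 1), replace = TRUE)
    expect_identical(clone_range(g[sample.int(length(g))]), clone_range(g))
    expect_identical(clone_range(g) == 0L, length(unique(g)) == 1L)
  }
})

test_that("cohort_normalize matches hand computation and sums to 1", {
  expect_equal(cohort_normalize(c(0, 0, 4)), c(0, 0, 1))
  expect_equal(cohort_normalize(c(0, 1, 2)), c(0, 0.5, 0.5))
  expect_equal(cohort_normalize(c(1)), 1)
  expect_error(cohort_normalize(c(0, 0)), "positive")
  set.seed(22)
  for (i in 1:50)
    expect_equal(sum(cohort_normalize(random_ddvector())), 1, tolerance = 1e-12)
})

test_that("clone_mdd is the cohort-weighted mean generation", {
  expect_equal(clone_mdd(c(0, 0, 4)), 2)
  expect_equal(clone_mdd(c(0, 1, 2)), 1.5)
  expect_equal(clone_mdd(c(0, 0, 0, 8)), 3)
})

test_that("clone_mdd of single-generation clones is unbiased under any thinning", {
  # all cells in generation g: mdd = g exactly whatever the recovered count
  set.seed(23)
  for (i in 1:10000) {
    g <- sample(1:6, 1)
    k <- rbinom(1, 2^g, runif(1, 0.2, 1))
    if (k == 0) next
    n <- numeric(g + 1); n[g + 1] <- k
    expect_identical(clone_mdd(n), as.numeric(g))
  }
})

test_that("clone_maxdd requires a fully quiescent clone", {
  expect_identical(clone_maxdd(c(3, 4, 4), c(1, 1, 1)), 4L)
  expect_identical(clone_maxdd(5, 1), 5L)
  expect_error(clone_maxdd(c(3, 4), c(1, 0)), "dividing")
})

test_that("filter_dd_clones keeps exactly the all-quiescent clones", {
  tab <- tiny_clone_table()
  kept <- filter_dd_clones(tab)
  expect_setequal(unique(kept$clone_id), "q1")
  all_mixed <- clone_table(data.frame(
    condition = "c", timepoint_h = 54, clone_id = c("a", "a"),
    generation = c(2, 2), n_cells = c(1, 1), quiescent = c(0, 1)))
  expect_identical(nrow(filter_dd_clones(all_mixed)), 0L)
  one_dd <- clone_table(data.frame(
    condition = "c", timepoint_h = 54, clone_id = "a",
    generation = 3, n_cells = 4, quiescent = 1))
  expect_identical(nrow(filter_dd_clones(one_dd)), 1L)
})

test_that("classify_clones orders mixed clones by the synchrony property", {
  mk <- function(gd, gq) clone_table(data.frame(
    condition = "c", timepoint_h = 54, clone_id = "m",
    generation = c(gd, gq), n_cells = 1, quiescent = c(0, 1)))
  expect_true(classify_clones(mk(4, 4))$ordered)
  expect_true(classify_clones(mk(3, 4))$ordered)
  expect_false(classify_clones(mk(5, 4))$ordered)
  cls <- classify_clones(tiny_clone_table())
  expect_setequal(cls$class[match(c("q1", "d1", "m1"), cls$clone_id)],
                  c("all-quiescent", "all-dividing", "mixed"))
})

test_that("population mean division number is the cohort-weighted mean", {
  expect_equal(mean_division_number(c(0, 0, 4)), 2)
  expect_equal(mean_division_number(c(2, 4)), 0.5)
  expect_equal(mean_division_number(c(1, 0, 0)), 0)
  expect_error(mean_division_number(c(0, 0)), "positive")
  # a population entirely in generation g has MDN g exactly
  for (g in 0:6) {
    counts <- numeric(g + 1); counts[g + 1] <- 2^g * 3
    expect_identical(mean_division_number(counts), as.numeric(g))
  }
})

test_that("population_mdd is the plateau (maximum) of the MDN timecourse", {
  tc <- list(c(4, 8, 0, 0), c(0, 4, 8, 2), c(0, 4, 8, 1))
  mdns <- vapply(tc, mean_division_number, numeric(1))
  expect_equal(population_mdd(tc), max(mdns))
  expect_equal(population_mdd(list(c(0, 2, 2))),
               mean_division_number(c(0, 2, 2)))
  expect_equal(population_mdd(list(c(1, 2), c(1, 2))),
               mean_division_number(c(1, 2)))
  expect_error(population_mdd(list()), "timepoints")
})

test_that("clone_summary aggregates per clone with mdd/maxdd only at DD", {
  summ <- clone_summary(tiny_clone_table())
  expect_identical(nrow(summ), 3L)
  q1 <- summ[summ$clone_id == "q1", ]
  expect_identical(q1$range, 1L)
  expect_identical(q1$maxdd, 4L)
  expect_equal(q1$mdd, clone_mdd(c(0, 0, 0, 2, 1)))
  expect_true(is.na(summ$mdd[summ$clone_id == "m1"]))
})
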