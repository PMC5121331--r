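# Shared fixtures built in code.

# random DD vector: counts over generations 0..(len-1), at least one positive
random_ddvector <- function(max_len = 6, max_count = 8) {
  len <- sample(1:max_len, 1)
  x <- rpois(len, 1.2)
  x[sample(len, 1)] <- x[sample(len, 1)] + sample(1:max_count, 1)
  x
}

# tiny clone table covering the three clone classes
tiny_clone_table <- function() {
  clone_table(data.frame(
    condition = "N4",
    timepoint_h = 62,
    clone_id = rep(c("q1", "d1", "m1"), c(2, 1, 2)),
    generation = c(3, 4, 2, 4, 4),
    n_cells = c(2, 1, 3, 1, 2),
    quiescent = c(1, 1, 0, 0, 1)),
    sampling_prob = c(N4 = 0.9))
}

# range of each row of an observed-subtree count matrix (NA when empty)
row_ranges <- function(s) {
  occ <- s > 0
  nonempty <- rowSums(occ) > 0
  first <- max.col(occ, ties.method = "first")
  last <- max.col(occ, ties.method = "last")
  out <- rep(NA_integer_, nrow(s))
  out[nonempty] <- last[nonempty] - first[nonempty]
  out
}

# exact cohort-mass check in integer arithmetic: sum t_i 2^(D-i) == 2^D
cohort_mass_is_one <- function(t) {
  D <- length(t) - 1L
  sum(t * 2^(D - (seq_along(t) - 1L))) == 2^D
}
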