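#' Clonal contributions to in vivo population expansion
#'
#' Desk-scale calculations linking a division-destiny probability function to
#' the clonal composition of an in vivo response, assuming concordant clonal
#' DD and minimal death: clones reaching DD in division i contribute
#' `N_i = f_i * mN0 * 2^i` progeny, so a small high-DD minority of clones
#' dominates the response.
#'
#' @name invivo_extrapolation
NULL

#' Clonal contribution curve
#'
#' Re-introduces expansion into a DD probability function: with
#' `N_i = f_i * mN0 * 2^i`, the percentage contribution of clones reaching
#' DD in division i is `100 * N_i / sum_j N_j`.  Clones are ordered by DD
#' descending (largest burst first) and both axes cumulated, yielding the
#' classic "few clones produce the bulk of the response" curve.  The
#' percentages are invariant to the scale `mN0`.
#'
#' @param f probabilities of a clone reaching DD in each division (will be
#'   normalized to sum to 1).
#' @param divisions matching division numbers (e.g. `4:19`).
#' @param mN0 mean initial (founder) cell number; default 1808.
#' @return data frame ordered by decreasing division: `division`,
#'   `pct_clones`, `contribution`, `cum_pct_clones`, `cum_contribution`.
#' @export
clonal_contribution_curve <- function(f, divisions, mN0 = 1808) {
  if (length(f) != length(divisions)) stop("lengths differ")
  if (any(f < 0) || sum(f) == 0) stop("'f' must be non-negative, not all zero")
  f <- f / sum(f)
  N <- f * mN0 * 2^divisions
  contribution <- 100 * N / sum(N)
  o <- order(divisions, decreasing = TRUE)
  out <- data.frame(division = divisions[o],
                    pct_clones = 100 * f[o],
                    contribution = contribution[o])
  out$cum_pct_clones <- cumsum(out$pct_clones)
  out$cum_contribution <- cumsum(out$contribution)
  out
}

#' Infer a binned DD distribution from clone sizes
#'
#' Assuming concordant DD and minimal death, a clone of `N` cells has
#' `DD = ceiling(log2(N))` (a single undivided cell has DD 0).  DD values
#' are histogrammed in bins of two divisions starting at the smallest
#' observed DD.
#'
#' @param sizes positive clone cell counts.
#' @param bin_width bin width in divisions (default 2).
#' @return data frame: `bin_start`, `bin_end` (inclusive), `count`; the
#'   per-clone DDs are attached as attribute `"dd"`.
#' @export
dd_from_clone_sizes <- function(sizes, bin_width = 2) {
  if (any(sizes < 1)) stop("clone sizes must be >= 1 cell")
  dd <- as.integer(ceiling(log2(sizes)))
  starts <- as.integer(seq(min(dd), max(dd), by = bin_width))
  bin <- starts[findInterval(dd, starts)]
  counts <- table(factor(bin, levels = starts))
  out <- data.frame(bin_start = starts,
                    bin_end = starts + bin_width - 1L,
                    count = as.integer(counts))
  attr(out, "dd") <- dd
  out
}
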