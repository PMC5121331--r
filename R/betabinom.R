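#' Beta-binomial distribution with intraclass-correlation parameterization
#'
#' Density and random generation for the beta-binomial distribution
#' parameterized by its mean success probability `prob` and the pairwise
#' (intraclass) correlation `rho` between the Bernoulli outcomes of any two
#' trials.  The mixing density is Beta(a, b) with
#' `a = prob * (1 - rho) / rho` and `b = (1 - prob) * (1 - rho) / rho`, so the
#' correlation between any pair of trials is exactly `rho`.  The limits are
#' handled analytically: `rho = 0` is the binomial distribution and `rho = 1`
#' is the two-point law where all trials share a single decision (all
#' successes with probability `prob`, all failures otherwise).
#'
#' This is the within-family shared-fate model: each of the `size` cells of a
#' clone in one generation progresses past that generation with probability
#' `prob`, and `rho` interpolates between fully independent and fully shared
#' division-destiny decisions.
#'
#' @param x number of successes (vectorized).
#' @param size number of trials (vectorized, recycled against `x`).
#' @param prob mean success probability, in \[0, 1\].
#' @param rho pairwise correlation, in \[0, 1\].
#' @param log if `TRUE`, return log-probabilities.
#' @return `dbetabinom` returns the probability mass; `rbetabinom` returns
#'   `n` random counts.
#' @examples
#' dbetabinom(1, 2, 0.5, 0)      # binomial limit: 0.5
#' dbetabinom(3, 3, 0.7, 1)      # shared-decision limit: 0.7
#' @export
dbetabinom <- function(x, size, prob, rho, log = FALSE) {
  if (length(prob) != 1L || length(rho) != 1L)
    stop("'prob' and 'rho' must be scalars")
  if (is.na(prob) || prob < 0 || prob > 1) stop("'prob' must be in [0, 1]")
  if (is.na(rho) || rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
  m <- max(length(x), length(size))
  x <- rep_len(x, m)
  size <- rep_len(size, m)
  if (any(size < 0)) stop("'size' must be non-negative")

  lp <- rep(-Inf, m)
  ok <- x >= 0 & x <= size & x == round(x)
  if (rho == 0) {
    lp[ok] <- dbinom(x[ok], size[ok], prob, log = TRUE)
  } else if (prob == 0) {
    lp[ok & x == 0] <- 0
  } else if (prob == 1) {
    lp[ok & x == size] <- 0
  } else if (rho == 1) {
    # all trials share one decision; size 0 is the empty (certain) event
    lp[ok & size == 0] <- 0
    lp[ok & size > 0 & x == size] <- log(prob)
    lp[ok & size > 0 & x == 0] <- pmax(lp[ok & size > 0 & x == 0], log(1 - prob))
  } else {
    a <- prob * (1 - rho) / rho
    b <- (1 - prob) * (1 - rho) / rho
    lp[ok] <- lchoose(size[ok], x[ok]) +
      lbeta(x[ok] + a, size[ok] - x[ok] + b) - lbeta(a, b)
  }
  if (log) lp else exp(lp)
}

#' @rdname dbetabinom
#' @param n number of draws.
#' @export
rbetabinom <- function(n, size, prob, rho) {
  if (length(prob) != 1L || length(rho) != 1L)
    stop("'prob' and 'rho' must be scalars")
  if (prob < 0 || prob > 1) stop("'prob' must be in [0, 1]")
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
  size <- rep_len(size, n)
  if (rho == 0) return(rbinom(n, size, prob))
  if (prob == 0) return(integer(n))
  if (prob == 1) return(size)
  if (rho == 1) {
    all_in <- runif(n) < prob
    return(ifelse(all_in, size, 0L))
  }
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  q <- rbeta(n, a, b)
  rbinom(n, size, q)
}
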