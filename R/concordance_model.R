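#' The beta-binomial correlated family-DD model
#'
#' Generative model for clonal family trees: starting from one founder
#' (generation 0), the `c_k` cells present in generation k progress past it
#' in a beta-binomially distributed number (probability `p_k`, within-family
#' correlation `rho`); cells that do not progress take their division destiny
#' (DD) at generation k and the progressing cells double into generation
#' k + 1.  Each DD cell of the realized full tree is then recovered
#' independently with sampling probability `r`.  The model predicts the
#' distribution of the clonal range among recovered (non-empty) families and
#' supports maximum-likelihood estimation of `rho`.
#'
#' @name concordance_model
NULL

#' Progression profile
#'
#' `p[k+1]` is the probability that a cell in generation k progresses past k
#' (does not take DD there); the final entry, at `max_depth`, is 0 so every
#' lineage terminates.
#'
#' @param p numeric vector of progression probabilities for generations
#'   `0 .. length(p) - 1`; last entry must be 0.
#' @return an object of class `dd_profile`.
#' @export
dd_profile <- function(p) {
  if (any(p < 0 | p > 1)) stop("progression probabilities must lie in [0, 1]")
  if (p[length(p)] != 0) stop("the final progression probability must be 0")
  structure(list(p = as.numeric(p), max_depth = length(p) - 1L),
            class = "dd_profile")
}

#' Estimate the progression profile from pooled DD counts
#'
#' From per-generation DD cell counts `n_k` pooled across families, the
#' cohort-corrected counts are `nt_j = n_j / 2^j` and the conditional
#' progression probability is
#' `p_k = sum_{j > k} nt_j / sum_{j >= k} nt_j`, with `p = 0` wherever no
#' cohort mass remains.  Because every cell is thinned by the same recovery
#' probability, the estimate is invariant to sampling, and the pooled
#' per-generation progression it encodes is reproduced by the family model
#' irrespective of `rho`.
#'
#' @param dd_counts DD cell counts per generation (element 1 = generation 0).
#' @param max_depth profile depth D; defaults to the highest occupied
#'   generation.
#' @return a [dd_profile()].
#' @export
estimate_progression <- function(dd_counts, max_depth = NULL) {
  if (any(dd_counts < 0) || all(dd_counts == 0))
    stop("DD counts must be non-negative with at least one positive entry")
  top <- max(which(dd_counts > 0)) - 1L
  if (is.null(max_depth)) max_depth <- top
  if (max_depth < top)
    stop("'max_depth' must be at least the highest occupied generation (", top, ")")
  nt <- c(dd_counts * 2^(-(seq_along(dd_counts) - 1)),
          rep(0, max_depth + 1L - length(dd_counts)))
  tails <- rev(cumsum(rev(nt)))            # sum_{j >= k} nt_j
  p <- numeric(max_depth + 1L)
  for (k in seq_len(max_depth)) {          # generation k-1; p_D stays 0
    denom <- tails[k]
    p[k] <- if (denom > 0) (denom - nt[k]) / denom else 0
  }
  dd_profile(p)
}

#' Concordance model
#'
#' Bundles a progression profile, the within-family DD correlation `rho`, and
#' the per-condition cell recovery probability `r`.
#'
#' @param profile a [dd_profile()].
#' @param rho within-family correlation, in \[0, 1\].
#' @param r sampling (recovery) probability, in (0, 1\].
#' @return an object of class `dd_model`.
#' @export
dd_model <- function(profile, rho, r = 1) {
  stopifnot(inherits(profile, "dd_profile"))
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
  if (r <= 0 || r > 1) stop("'r' must be in (0, 1]")
  structure(list(profile = profile, rho = rho, r = r), class = "dd_model")
}

## ---- full-tree enumeration ----------------------------------------------

.tree_cache <- new.env(parent = emptyenv())

#' Enumerate all full family trees of a given depth
#'
#' A full tree of depth D is a DD-count vector `(t_0, ..., t_D)` consistent
#' with binary division: with `c_0 = 1` and `c_{i+1} = 2 (c_i - t_i)`,
#' every `0 <= t_i <= c_i` and all remaining cells stop at D
#' (`t_D = c_D`).  Every enumerated tree has cohort mass
#' `sum_i t_i 2^-i = 1` exactly.  The enumeration (brute force, memoized per
#' depth) is the support of the full-tree likelihood.
#'
#' @param max_depth D, with `0 <= D <= 8` (the count grows rapidly: 1, 2, 4,
#'   10, 36, 202, 1828, 27338 trees for D = 0..7).
#' @return integer matrix, one tree per row, `D + 1` columns (`t` counts);
#'   attribute `"cells"` holds the matching `c` matrix.
#' @export
enumerate_full_trees <- function(max_depth) {
  if (max_depth < 0 || max_depth != round(max_depth))
    stop("'max_depth' must be a non-negative integer")
  if (max_depth > 8)
    stop("enumeration for depth > 8 is not supported (tree count explodes)")
  key <- as.character(max_depth)
  if (!is.null(.tree_cache[[key]])) return(.tree_cache[[key]])
  rec <- function(c_now, depth_left) {
    if (depth_left == 0L) return(list(c_now))
    out <- list()
    for (t in 0:c_now) {
      for (tail in rec(2L * (c_now - t), depth_left - 1L))
        out[[length(out) + 1L]] <- c(t, tail)
    }
    out
  }
  trees <- do.call(rbind, rec(1L, as.integer(max_depth)))
  cells <- matrix(0L, nrow(trees), ncol(trees))
  cells[, 1] <- 1L
  if (max_depth >= 1)
    for (i in seq_len(max_depth))
      cells[, i + 1L] <- 2L * (cells[, i] - trees[, i])
  attr(trees, "cells") <- cells
  .tree_cache[[key]] <- trees
  trees
}

tree_log_likelihoods <- function(trees, profile, rho) {
  cells <- attr(trees, "cells")
  p <- profile$p
  ll <- numeric(nrow(trees))
  for (i in seq_len(ncol(trees)))
    ll <- ll + dbetabinom(cells[, i] - trees[, i], cells[, i], p[i], rho,
                          log = TRUE)
  ll
}

#' Likelihood of a full family tree
#'
#' Product over generations of the beta-binomial probability that, of the
#' `c_i` cells present in generation i, `c_i - t_i` progress past it.
#' Likelihoods sum to 1 over [enumerate_full_trees()] of the profile's depth.
#'
#' @param tree DD-count vector `(t_0, ..., t_D)` of a full tree.
#' @param model a [dd_model()].
#' @return the tree probability.
#' @export
full_tree_likelihood <- function(tree, model) {
  stopifnot(inherits(model, "dd_model"))
  D <- model$profile$max_depth
  if (length(tree) != D + 1L)
    stop("tree length must equal profile depth + 1 (", D + 1L, ")")
  cells <- c(1L, numeric(D))
  if (D >= 1)
    for (i in seq_len(D)) {
      cells[i + 1L] <- 2L * (cells[i] - tree[i])
      if (tree[i] > cells[i] || cells[i + 1L] < 0)
        stop("tree is inconsistent with binary-division dynamics")
    }
  if (tree[D + 1L] != cells[D + 1L])
    stop("tree does not terminate at depth ", D)
  m <- matrix(as.integer(tree), nrow = 1)
  attr(m, "cells") <- matrix(as.integer(cells), nrow = 1)
  exp(tree_log_likelihoods(m, model$profile, model$rho))
}

#' Likelihood of an observed subtree given its full tree
#'
#' Independent binomial thinning per generation: each of the `t_i` DD cells
#' is recovered with probability `r`, so
#' `L(S | T, r) = prod_i choose(t_i, s_i) r^s_i (1-r)^(t_i - s_i)`.
#'
#' @param s observed DD counts per generation.
#' @param tree full-tree DD counts (same length, `s <= tree` elementwise).
#' @param r sampling probability in (0, 1\].
#' @return the sampling probability of `s`.
#' @export
subtree_sampling_likelihood <- function(s, tree, r) {
  if (length(s) != length(tree)) stop("'s' and 'tree' must have equal length")
  if (any(s > tree)) stop("observed counts exceed the full tree (s_i > t_i)")
  if (r <= 0 || r > 1) stop("'r' must be in (0, 1]")
  prod(dbinom(s, tree, r))
}

## ---- range distribution --------------------------------------------------

# P(observed range = f), f = 0..D, and P(empty sample), for one tree with
# occupancy probabilities q_i = 1 - (1-r)^{t_i}.  Uses
# P(min = a, max = b) = q_a q_b prod_{i outside [a,b]} (1 - q_i)  (a < b)
#                     = q_a     prod_{i != a}          (1 - q_i)  (a = b),
# which equals the subtree sum of the sampling likelihoods because thinning
# is independent across generations.
tree_range_probs <- function(t, r, D) {
  occ <- which(t > 0)
  q <- 1 - (1 - r)^t[occ]
  k <- length(q)
  pr <- numeric(D + 1L)                 # ranges 0..D
  none <- prod(1 - q)
  for (ai in seq_len(k)) {
    a <- occ[ai]
    for (bi in ai:k) {
      b <- occ[bi]
      outside <- prod(1 - q[c(seq_len(ai - 1L),
                              if (bi < k) (bi + 1L):k else integer(0))])
      p_ab <- if (ai == bi) q[ai] * outside else q[ai] * q[bi] * outside
      f <- b - a
      pr[f + 1L] <- pr[f + 1L] + p_ab
    }
  }
  list(range = pr, empty = none)
}

#' Model-predicted distribution of the clonal range
#'
#' Sums over all full trees of depth D and, analytically, over all sampled
#' subtrees: `P(Range = f)` is proportional to
#' `sum_T L(T) P_T(observed range = f)` where the per-tree probability
#' follows from independent per-generation recovery.  Mass is conditioned on
#' a non-empty sample (clones with no recovered progeny are unobservable) and
#' renormalized.
#'
#' @param model a [dd_model()] (supplies `p`, `rho` and `r`).
#' @param max_depth enumeration depth; defaults to the profile's depth.
#' @return data frame of class `range_distribution`: `range`, `prob`.
#' @export
range_distribution <- function(model, max_depth = NULL) {
  stopifnot(inherits(model, "dd_model"))
  if (is.null(max_depth)) max_depth <- model$profile$max_depth
  if (max_depth != model$profile$max_depth)
    stop("'max_depth' must match the profile depth")
  trees <- enumerate_full_trees(max_depth)
  w <- exp(tree_log_likelihoods(trees, model$profile, model$rho))
  pr <- numeric(max_depth + 1L)
  mass <- 0
  for (j in seq_len(nrow(trees))) {
    if (w[j] <= 0) next
    rp <- tree_range_probs(trees[j, ], model$r, max_depth)
    pr <- pr + w[j] * rp$range
    mass <- mass + w[j] * (1 - rp$empty)
  }
  out <- data.frame(range = 0:max_depth, prob = pr / mass)
  class(out) <- c("range_distribution", "data.frame")
  out
}

#' Finite-sample confidence envelope for a range distribution
#'
#' For each range value f, the central interval of
#' `Binomial(n_families, P(f)) / n_families` -- the spread expected when the
#' model prediction is observed in an experiment recovering `n_families`
#' clonal families.
#'
#' @param dist a [range_distribution()].
#' @param n_families number of experimentally recovered families (>= 1).
#' @param level coverage level (default 0.95).
#' @return the input with `lower` and `upper` columns appended.
#' @export
range_distribution_ci <- function(dist, n_families, level = 0.95) {
  stopifnot(inherits(dist, "range_distribution"), n_families >= 1)
  alpha <- (1 - level) / 2
  dist$lower <- qbinom(alpha, n_families, dist$prob) / n_families
  dist$upper <- qbinom(1 - alpha, n_families, dist$prob) / n_families
  dist
}

## ---- rho fitting ---------------------------------------------------------

#' Maximum-likelihood estimation of the within-family DD correlation
#'
#' Fits `rho` to a collection of observed (sampled) family DD-count vectors
#' by maximizing the marginal likelihood
#' `sum_clones log( sum_T L(T | p, rho) L(S | T, r) / P(non-empty) )`,
#' where the inner sum runs over all full trees of the profile depth and the
#' conditioning reflects that families with no recovered progeny are never
#' observed.  A deterministic grid search (step `grid_step`) is followed by
#' golden-section refinement in the bracketing interval; estimates at the
#' boundary are reported as exactly 0 or 1.
#'
#' @param subtrees matrix of observed DD counts, one clone per row, columns =
#'   generations `0 .. D`; or a list of vectors (padded with zeros to D + 1).
#' @param profile a [dd_profile()] fitted from the same pooled data.
#' @param r sampling probability in (0, 1\].
#' @param grid_step rho grid resolution (default 0.01).
#' @return list of class `rho_fit`: `rho` (the MLE), `loglik` at the MLE,
#'   and `grid` (data frame `rho`, `loglik` -- the profile-likelihood curve).
#' @export
fit_rho <- function(subtrees, profile, r, grid_step = 0.01) {
  stopifnot(inherits(profile, "dd_profile"))
  D <- profile$max_depth
  if (is.list(subtrees)) {
    subtrees <- do.call(rbind, lapply(subtrees, function(s) {
      if (length(s) > D + 1L) stop("observed subtree deeper than the profile")
      c(s, numeric(D + 1L - length(s)))
    }))
  }
  if (ncol(subtrees) != D + 1L)
    stop("subtree matrix must have profile depth + 1 columns")
  subtrees <- subtrees[rowSums(subtrees) > 0, , drop = FALSE]
  if (nrow(subtrees) == 0) stop("no non-empty observed families")
  trees <- enumerate_full_trees(D)
  n_tree <- nrow(trees)
  n_clone <- nrow(subtrees)
  # sampling likelihoods L(S_clone | T, r): fixed across rho
  M <- matrix(0, n_clone, n_tree)
  for (j in seq_len(n_tree)) {
    tj <- matrix(trees[j, ], n_clone, D + 1L, byrow = TRUE)
    M[, j] <- exp(rowSums(dbinom(subtrees, tj, r, log = TRUE)))
  }
  log_empty <- rowSums(trees) * log1p(-r)   # per-tree P(no cell recovered)
  loglik <- function(rho) {
    w <- exp(tree_log_likelihoods(trees, profile, rho))
    p_obs <- 1 - sum(w * exp(log_empty))
    lik <- as.vector(M %*% w)
    if (any(lik <= 0) || p_obs <= 0) return(-Inf)
    sum(log(lik)) - n_clone * log(p_obs)
  }
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, loglik, numeric(1))
  best <- which.max(ll)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- optimize(loglik, c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.35)
  rho_hat <- opt$maximum
  ll_hat <- opt$objective
  if (ll[best] >= ll_hat) {
    rho_hat <- grid[best]
    ll_hat <- ll[best]
  }
  if (rho_hat < grid_step / 10) rho_hat <- 0
  if (rho_hat > 1 - grid_step / 10) rho_hat <- 1
  structure(list(rho = rho_hat, loglik = ll_hat,
                 grid = data.frame(rho = grid, loglik = ll)),
            class = "rho_fit")
}

#' @export
print.rho_fit <- function(x, ...) {
  cat("Within-family DD correlation fit\n")
  cat(sprintf("  rho MLE: %.4f  (log-likelihood %.3f)\n", x$rho, x$loglik))
  invisible(x)
}
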