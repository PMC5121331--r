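#' Synthetic clone tables with the assay's statistical structure
#'
#' Forward sampler of the correlated family-DD model plus the observation
#' layer of the multiplex clonal assay: founder cells divide 0-7 times with
#' within-family beta-binomial correlated progression, wells are harvested at
#' fixed times (cells past their DD generation are quiescent, lineages still
#' progressing appear as dividing cells at their current generation), every
#' cell is recovered independently with probability r, and the quiescence
#' flag is flipped with a small misclassification probability emulating
#' size-based gating error.
#'
#' @name synthetic_data
NULL

#' Simulate full family trees from the concordance model
#'
#' Generation by generation: of the `c_k` cells present, a beta-binomial
#' `(c_k, p_k, rho)` number progresses; the remainder take DD at k, and
#' progressing cells double.  Returns DD-count vectors `(t_0, ..., t_D)`.
#'
#' @param n number of trees.
#' @param profile a [dd_profile()].
#' @param rho within-family correlation in \[0, 1\].
#' @return integer matrix `n x (D + 1)`; every row has cohort mass 1.
#' @export
simulate_full_trees <- function(n, profile, rho) {
  stopifnot(inherits(profile, "dd_profile"))
  D <- profile$max_depth
  t <- matrix(0L, n, D + 1L)
  c_now <- rep(1L, n)
  if (D >= 1) {
    for (k in seq_len(D)) {
      prog <- rbetabinom(n, c_now, profile$p[k], rho)
      t[, k] <- c_now - prog
      c_now <- 2L * as.integer(prog)
    }
  }
  t[, D + 1L] <- c_now
  t
}

#' Binomial thinning of full trees into observed subtrees
#'
#' Each DD cell is recovered independently with probability `r`.
#'
#' @param trees matrix of full-tree DD counts (rows = families).
#' @param r sampling probability in (0, 1\].
#' @param drop_empty drop families with no recovered cell (default `TRUE`).
#' @return matrix of observed DD counts.
#' @export
thin_trees <- function(trees, r, drop_empty = TRUE) {
  if (r <= 0 || r > 1) stop("'r' must be in (0, 1]")
  s <- matrix(rbinom(length(trees), as.vector(trees), r),
              nrow(trees), ncol(trees))
  if (drop_empty) s <- s[rowSums(s) > 0, , drop = FALSE]
  s
}

#' Build a progression profile from a founder-equivalent DD distribution
#'
#' `pi[i]` is the probability that a founder-equivalent takes DD in
#' generation `generations[i]`; the conditional progression probabilities
#' follow as tail ratios.
#'
#' @param pi probabilities (summing to 1) of DD per generation.
#' @param generations matching 0-based generations.
#' @return a [dd_profile()] of depth `max(generations)`.
#' @export
profile_from_dd_distribution <- function(pi, generations) {
  if (length(pi) != length(generations)) stop("lengths differ")
  if (abs(sum(pi) - 1) > 1e-8) stop("'pi' must sum to 1")
  D <- max(generations)
  full <- numeric(D + 1L)
  full[generations + 1L] <- pi
  tails <- rev(cumsum(rev(full)))
  p <- numeric(D + 1L)
  for (k in seq_len(D))
    p[k] <- if (tails[k] > 0) (tails[k] - full[k]) / tails[k] else 0
  dd_profile(p)
}

#' Default simulation configuration: the four-condition stimulation study
#'
#' Four conditions (N4 peptide alone and with anti-CD28, IL-2, or both) with
#' founder inputs 96, 224, 96 and 224, harvests at 54, 62 and 72 h, cell
#' recovery probability 0.9 per condition, within-family correlation 0.9,
#' and 4\% quiescence misclassification.  DD mass sits in generations 2-7
#' with mean DD increasing from about 3.5 (N4) to about 5.5 (all three
#' stimuli), the regime of the in vitro assay.  Division timing uses a first
#' division at 26 h and 8 h per subsequent division.
#'
#' @return a list understood by [simulate_clone_table()].
#' @export
default_simulation_config <- function() {
  list(
    conditions = list(
      list(name = "N4", n_founders = 96, rho = 0.9, r = 0.9,
           profile = profile_from_dd_distribution(
             c(0.15, 0.35, 0.35, 0.15), 2:5)),
      list(name = "N4+aCD28", n_founders = 224, rho = 0.9, r = 0.9,
           profile = profile_from_dd_distribution(
             c(0.20, 0.35, 0.30, 0.15), 3:6)),
      list(name = "N4+IL2", n_founders = 96, rho = 0.9, r = 0.9,
           profile = profile_from_dd_distribution(
             c(0.15, 0.30, 0.35, 0.20), 3:6)),
      list(name = "N4+aCD28+IL2", n_founders = 224, rho = 0.9, r = 0.9,
           profile = profile_from_dd_distribution(
             c(0.15, 0.35, 0.35, 0.15), 4:7))),
    harvest_times = c(54, 62, 72),
    misclass_rate = 0.04,
    first_division_h = 26,
    division_h = 8)
}

#' Simulate a clone table
#'
#' Per founder: a full tree is drawn, the founder's well is assigned a
#' harvest time (founders split evenly across harvests), cells whose DD
#' generation has been reached by harvest are quiescent while lineages still
#' progressing appear as dividing cells at the current generation; each cell
#' is recovered with probability r and its quiescence flag flipped with the
#' misclassification probability.  Families with no recovered cell are
#' dropped (with a message), mirroring incomplete recovery in the assay.
#'
#' @param config list as produced by [default_simulation_config()].
#' @param seed optional integer seed; fixed seed gives an identical table.
#' @return a [clone_table()] with `sampling_prob` and `founder_input`
#'   attributes.
#' @export
simulate_clone_table <- function(config = default_simulation_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mis <- config$misclass_rate
  gens_done <- function(h) {
    g <- floor((h - config$first_division_h) / config$division_h) + 1
    max(0, g)
  }
  rows <- list()
  dropped <- 0L
  for (cond in config$conditions) {
    trees <- simulate_full_trees(cond$n_founders, cond$profile, cond$rho)
    D <- cond$profile$max_depth
    harvest <- rep_len(config$harvest_times, cond$n_founders)
    for (f in seq_len(cond$n_founders)) {
      t <- trees[f, ]
      g <- gens_done(harvest[f])
      # quiescent DD cells up to generation g; still-progressing cells sit
      # (dividing) at generation g
      cells_gen <- integer(0); cells_q <- integer(0); cells_n <- integer(0)
      for (i in 0:min(g, D)) {
        if (t[i + 1L] > 0) {
          cells_gen <- c(cells_gen, i); cells_q <- c(cells_q, 1L)
          cells_n <- c(cells_n, t[i + 1L])
        }
      }
      if (g <= D) {
        c_now <- 1L
        if (g >= 1) for (i in seq_len(g)) c_now <- 2L * (c_now - t[i])
        div_n <- c_now - t[g + 1L]   # cells not yet at DD at generation g
        if (g < D && div_n > 0) {
          cells_gen <- c(cells_gen, g); cells_q <- c(cells_q, 0L)
          cells_n <- c(cells_n, div_n)
        } else if (g == D && div_n > 0) {
          # depth D forces DD; treat as quiescent at D
          cells_gen <- c(cells_gen, g); cells_q <- c(cells_q, 1L)
          cells_n <- c(cells_n, div_n)
        }
      }
      # recovery and misclassification, cell by cell in aggregate
      rec <- rbinom(length(cells_n), cells_n, cond$r)
      if (sum(rec) == 0) { dropped <- dropped + 1L; next }
      flip <- rbinom(length(rec), rec, mis)
      keepq <- rec - flip
      gen_out <- c(cells_gen, cells_gen)
      q_out <- c(cells_q, 1L - cells_q)
      n_out <- c(keepq, flip)
      ok <- n_out > 0
      if (!any(ok)) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = "sim1",
        condition = cond$name,
        timepoint_h = harvest[f],
        clone_id = sprintf("%s_c%04d", cond$name, f),
        generation = gen_out[ok],
        n_cells = n_out[ok],
        quiescent = q_out[ok],
        stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0)
    message(dropped, " clone(s) had no recovered progeny and were dropped")
  tab <- do.call(rbind, rows)
  r_by <- vapply(config$conditions, function(z) z$r, numeric(1))
  names(r_by) <- vapply(config$conditions, function(z) z$name, character(1))
  f_by <- vapply(config$conditions, function(z) z$n_founders, numeric(1))
  names(f_by) <- names(r_by)
  clone_table(tab, sampling_prob = r_by, founder_input = f_by)
}

#' Simulate families under the independent-additivity hypothesis
#'
#' Each family's DD vector is the convolution of an independent draw from a
#' base-condition sampler and an increment sampler -- the generative model
#' when a costimulus adds an independent expansion effect to every clone.
#'
#' @param base_sampler,increment_sampler zero-argument functions returning a
#'   DD vector.
#' @param n number of families.
#' @return list of `n` DD vectors.
#' @export
simulate_additive_condition <- function(base_sampler, increment_sampler, n) {
  lapply(seq_len(n), function(i)
    dd_convolve(base_sampler(), increment_sampler()))
}
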