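#' Per-clone and population division-destiny statistics
#'
#' Summary statistics of division destiny (DD): the clonal range, the
#' cohort-normalized mean DD (mDD), the maximum DD of fully quiescent clones,
#' and population mean division numbers.  All generation counts are 0-based
#' (founder = generation 0) and cohort correction divides cell counts by
#' `2^generation` to convert to founder-cell equivalents.
#'
#' @name clonal_statistics
NULL

expand_generations <- function(generation, n_cells) {
  rep(generation, times = n_cells)
}

#' Clonal range
#'
#' Maximum minus minimum generation over all detected progeny of one clone
#' (quiescent and dividing alike).  Range 0 is a concordant clone.
#'
#' @param generation generations of the clone's detected cells (one entry per
#'   row), possibly weighted by `n_cells`.
#' @param n_cells optional per-row cell counts (only occupancy matters).
#' @return non-negative integer.
#' @export
clone_range <- function(generation, n_cells = NULL) {
  if (!is.null(n_cells)) generation <- generation[n_cells > 0]
  if (length(generation) == 0)
    stop("clone has no detected progeny; range is undefined")
  as.integer(max(generation) - min(generation))
}

#' Cohort-normalize per-generation DD counts
#'
#' `q[i] = (n[i] / 2^(i-1)) / sum_j (n[j] / 2^(j-1))` with element 1 holding
#' generation 0.  The renormalization excludes cells lost to incomplete
#' recovery: uniform binomial thinning leaves `q` unbiased.  The output sums
#' to 1 exactly.
#'
#' @param n non-negative integer vector of DD cell counts per generation.
#' @return probability vector of the same length.
#' @export
cohort_normalize <- function(n) {
  if (any(n < 0) || all(n == 0))
    stop("DD counts must be non-negative with at least one positive entry")
  w <- n * 2^(-(seq_along(n) - 1))
  w / sum(w)
}

#' Cohort-normalized mean DD of one clone
#'
#' `sum_i i * q[i]` with `q` from [cohort_normalize()].
#'
#' @inheritParams cohort_normalize
#' @return mean DD generation (real, >= 0).
#' @export
clone_mdd <- function(n) {
  q <- cohort_normalize(n)
  sum((seq_along(q) - 1) * q)
}

#' Maximum DD of a fully quiescent clone
#'
#' The largest generation observed within a clone in which all cells have
#' reached DD; defined only when every detected cell is quiescent.
#'
#' @param generation generations of the clone's cells.
#' @param quiescent logical/0-1 flags per cell (or per row).
#' @return non-negative integer.
#' @export
clone_maxdd <- function(generation, quiescent) {
  if (length(generation) == 0) stop("clone has no detected progeny")
  if (!all(as.logical(quiescent)))
    stop("clone has dividing cells and has not reached division destiny")
  as.integer(max(generation))
}

#' Retain only clones whose every detected cell is quiescent
#'
#' Pools timepoints within condition: a clone qualifies if all its detected
#' progeny, at its harvest, are flagged quiescent.  May return an empty table.
#'
#' @param table a [clone_table()].
#' @return a [clone_table()] with only fully quiescent (DD) clones.
#' @export
filter_dd_clones <- function(table) {
  stopifnot(inherits(table, "clone_table"))
  all_q <- tapply(table$quiescent, table$clone_id, function(z) all(z == 1L))
  keep <- table$clone_id %in% names(all_q)[all_q]
  out <- table[keep, , drop = FALSE]
  attributes(out)[c("sampling_prob", "founder_input")] <-
    attributes(table)[c("sampling_prob", "founder_input")]
  class(out) <- class(table)
  out
}

#' Classify clones by quiescence composition
#'
#' Each clone is `all-quiescent`, `all-dividing` or `mixed`.  For mixed
#' clones, `ordered` is `TRUE` when no dividing cell lies in a later
#' generation than any quiescent cell of the same clone (dividing progeny in
#' the same or a previous generation relative to the quiescent cells), the
#' signature of synchronous within-clone division.
#'
#' @param table a [clone_table()].
#' @return data frame with one row per clone: `clone_id`, `condition`,
#'   `class`, `ordered` (`NA` unless mixed).
#' @export
classify_clones <- function(table) {
  stopifnot(inherits(table, "clone_table"))
  split_rows <- split(seq_len(nrow(table)), table$clone_id)
  out <- lapply(names(split_rows), function(id) {
    rows <- table[split_rows[[id]], , drop = FALSE]
    gq <- expand_generations(rows$generation[rows$quiescent == 1L],
                             rows$n_cells[rows$quiescent == 1L])
    gd <- expand_generations(rows$generation[rows$quiescent == 0L],
                             rows$n_cells[rows$quiescent == 0L])
    cls <- if (length(gd) == 0) "all-quiescent"
           else if (length(gq) == 0) "all-dividing"
           else "mixed"
    data.frame(clone_id = id, condition = rows$condition[1], class = cls,
               ordered = if (cls == "mixed") max(gd) <= min(gq) else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-clone summary table
#'
#' One row per clone with its detected cell count, range, class, and (for
#' fully quiescent clones) mDD and maxDD.
#'
#' @param table a [clone_table()].
#' @return data frame: `clone_id`, `condition`, `n_detected`, `range`,
#'   `class`, `ordered`, `mdd`, `maxdd` (the last two `NA` unless the clone
#'   is all-quiescent).
#' @export
clone_summary <- function(table) {
  stopifnot(inherits(table, "clone_table"))
  cls <- classify_clones(table)
  split_rows <- split(seq_len(nrow(table)), table$clone_id)
  stats <- lapply(names(split_rows), function(id) {
    rows <- table[split_rows[[id]], , drop = FALSE]
    gens <- expand_generations(rows$generation, rows$n_cells)
    all_q <- all(rows$quiescent == 1L)
    n <- tabulate(gens + 1L, nbins = max(gens) + 1L)
    data.frame(clone_id = id,
               n_detected = length(gens),
               range = clone_range(gens),
               mdd = if (all_q) clone_mdd(n) else NA_real_,
               maxdd = if (all_q) clone_maxdd(gens, rows$quiescent[
                 rep(seq_len(nrow(rows)), rows$n_cells)]) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, stats)
  out <- merge(cls, stats, by = "clone_id", sort = TRUE)
  out[c("clone_id", "condition", "n_detected", "range", "class", "ordered",
        "mdd", "maxdd")]
}

#' Population mean division number at one timepoint
#'
#' With cohort numbers `C[i] = count[i] / 2^(i-1)` (starting-cell
#' equivalents), returns the cohort-weighted mean generation
#' `sum_i (i-1) * C[i] / sum_i C[i]`.  Assuming little death this rises with
#' time and plateaus when cells reach DD.
#'
#' @param counts cell counts per generation (element 1 = generation 0).
#' @return mean division number (real).
#' @export
mean_division_number <- function(counts) {
  if (any(counts < 0) || all(counts == 0))
    stop("counts must be non-negative with at least one positive entry")
  gen <- seq_along(counts) - 1
  C <- counts * 2^(-gen)
  sum(gen * C) / sum(C)
}

#' Population mean division destiny over a timecourse
#'
#' The maximum mean division number over all timepoints -- the plateau of the
#' division timecourse.
#'
#' @param timecourse a list (or matrix with timepoints in rows) of
#'   per-generation cell counts.
#' @return population mDD (real).
#' @export
population_mdd <- function(timecourse) {
  if (is.matrix(timecourse))
    timecourse <- split(timecourse, row(timecourse))
  if (length(timecourse) == 0) stop("timecourse has no timepoints")
  max(vapply(timecourse, mean_division_number, numeric(1)))
}
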