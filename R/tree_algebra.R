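#' Division-destiny vectors and the tree-addition algebra
#'
#' A DD vector `x` is an integer vector whose element `x[i]` counts the
#' quiescent (division-destiny, DD) cells of a clonal family in generation
#' `i - 1` (element 1 is generation 0, the founder).  A family tree is a
#' rooted binary tree whose internal vertices are dividing cells and whose
#' leaves are quiescent cells at depth equal to their generation; its DD
#' vector is the generating-function coefficient vector of its leaves.
#'
#' Concatenating two family trees -- appending the second tree at any
#' final-cell partition of vertices of the first -- always yields a tree whose
#' DD vector is the convolution of the two input DD vectors, regardless of the
#' interlacing plan.  This makes DD vectors, not tree shapes, the currency of
#' signal-addition analysis.
#'
#' @name dd_vector
NULL

check_ddvector <- function(x) {
  if (length(x) == 0 || any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("a DD vector must be a non-negative integer vector")
  if (all(x == 0)) stop("a DD vector must have at least one positive entry")
  invisible(x)
}

#' Convolve two DD vectors
#'
#' The DD vector of the concatenation (sum) of two family trees:
#' `v[i] = sum_j x[j] * y[i - j]` on 0-based generations.  Cohort mass
#' `sum_i x[i] 2^-(i-1)` multiplies under convolution, and the identity
#' element is `c(1)` (a founder that never divides).  Integer arithmetic
#' throughout, so the result is exact.
#'
#' @param x,y DD vectors (element 1 = generation 0).
#' @return the convolved DD vector, length `length(x) + length(y) - 1`.
#' @examples
#' dd_convolve(c(0, 2), c(0, 2))     # (0, 0, 4)
#' dd_convolve(c(0, 1, 2), c(0, 2))  # (0, 0, 2, 4)
#' @export
dd_convolve <- function(x, y) {
  check_ddvector(x); check_ddvector(y)
  v <- numeric(length(x) + length(y) - 1L)
  for (j in seq_along(x)) {
    if (x[j] > 0) {
      idx <- j + seq_along(y) - 1L
      v[idx] <- v[idx] + x[j] * y
    }
  }
  if (is.integer(x) && is.integer(y) && max(v) <= .Machine$integer.max)
    storage.mode(v) <- "integer"
  v
}

#' Maximum division destiny of a DD vector
#'
#' The largest generation holding a quiescent cell.  Additive under
#' convolution: `dd_maxdd(dd_convolve(x, y)) == dd_maxdd(x) + dd_maxdd(y)`.
#'
#' @param x a DD vector.
#' @return integer generation (0-based).
#' @export
dd_maxdd <- function(x) {
  check_ddvector(x)
  max(which(x > 0)) - 1L
}

#' Cohort-normalized mean division destiny of a DD vector
#'
#' Generations weighted by cohort-corrected counts `x[i] * 2^-(i-1)`
#' (founder-cell equivalents), so that cell expansion does not bias the mean.
#' Additive under convolution: `dd_mdd(x * y) == dd_mdd(x) + dd_mdd(y)`.
#'
#' @param x a DD vector.
#' @return mean DD generation (real, >= 0).
#' @export
dd_mdd <- function(x) {
  check_ddvector(x)
  gen <- seq_along(x) - 1
  w <- x * 2^(-gen)
  sum(gen * w) / sum(w)
}

#' Cohort mass of a DD vector
#'
#' `sum_i x[i] * 2^-(i-1)`; equals 1 exactly for the DD vector of any full
#' binary-division family tree (each leaf contributes its founder-equivalent).
#'
#' @param x a DD vector.
#' @return the cohort mass (real).
#' @export
dd_cohort_mass <- function(x) {
  check_ddvector(x)
  sum(x * 2^(-(seq_along(x) - 1)))
}

## ---- explicit trees ------------------------------------------------------

#' Explicit family trees
#'
#' An explicit tree is a nested list: a leaf is `list()` and an internal
#' vertex (a dividing cell) is a list of exactly two child subtrees.  Leaf
#' generation equals leaf depth.  Vertices are addressed by paths: integer
#' vectors of child indices from the root (the root is the empty path).
#'
#' @param max_depth depth at which lineages are forced to stop dividing.
#' @param p_divide probability that a cell above `max_depth` divides.
#' @return `random_tree` returns an explicit tree.
#' @export
random_tree <- function(max_depth, p_divide = 0.6) {
  if (max_depth < 0) stop("'max_depth' must be >= 0")
  build <- function(depth) {
    if (depth >= max_depth || runif(1) >= p_divide) return(structure(list(), class = "dd_tree_node"))
    structure(list(build(depth + 1L), build(depth + 1L)), class = "dd_tree_node")
  }
  build(0L)
}

is_leaf <- function(node) length(node) == 0L

tree_leaf_depths <- function(node, depth = 0L) {
  if (is_leaf(node)) return(depth)
  c(tree_leaf_depths(node[[1L]], depth + 1L),
    tree_leaf_depths(node[[2L]], depth + 1L))
}

#' DD vector of an explicit tree
#'
#' Counts leaves (quiescent cells) per generation.
#'
#' @param tree an explicit tree (see [random_tree()]).
#' @return a DD vector (element 1 = generation 0).
#' @export
as_ddvector <- function(tree) {
  d <- tree_leaf_depths(tree)
  tabulate(d + 1L, nbins = max(d) + 1L)
}

subtree_at <- function(tree, path) {
  node <- tree
  for (i in path) {
    if (is_leaf(node)) stop("path descends below a leaf")
    node <- node[[i]]
  }
  node
}

path_key <- function(path) paste(path, collapse = ".")

#' Random final-cell partition plan
#'
#' Draws a set of vertices of `tree` whose descendant leaves partition all
#' leaves (an antichain covering every leaf): descending from the root, each
#' vertex is either selected (probability `stop_prob`, always at leaves) or
#' both its children are descended into.
#'
#' @param tree an explicit tree.
#' @param stop_prob per-vertex selection probability.
#' @return a list of vertex paths (integer vectors; the root is `integer(0)`).
#' @export
random_partition_plan <- function(tree, stop_prob = 0.4) {
  plan <- list()
  walk <- function(node, path) {
    if (is_leaf(node) || runif(1) < stop_prob) {
      plan[[length(plan) + 1L]] <<- path
    } else {
      walk(node[[1L]], c(path, 1L))
      walk(node[[2L]], c(path, 2L))
    }
  }
  walk(tree, integer(0))
  plan
}

validate_plan <- function(tree, plan) {
  keys <- vapply(plan, path_key, character(1))
  if (anyDuplicated(keys)) stop("interlacing plan repeats a vertex")
  # every leaf must have exactly one ancestor-or-self in the plan
  cover <- function(node, path, n_anc) {
    n_anc <- n_anc + (path_key(path) %in% keys)
    if (is_leaf(node)) {
      if (n_anc != 1L)
        stop("interlacing plan is not a final-cell partition (a leaf is covered ",
             n_anc, " times)")
      return(invisible())
    }
    cover(node[[1L]], c(path, 1L), n_anc)
    cover(node[[2L]], c(path, 2L), n_anc)
  }
  # plan vertices must exist
  lapply(plan, function(p) subtree_at(tree, p))
  cover(tree, integer(0), 0L)
  invisible(TRUE)
}

append_at_leaves <- function(tree, sub) {
  if (is_leaf(tree)) return(sub)
  structure(list(append_at_leaves(tree[[1L]], sub),
                 append_at_leaves(tree[[2L]], sub)),
            class = "dd_tree_node")
}

#' Concatenate two explicit family trees under an interlacing plan
#'
#' Implements tree addition: at every vertex of `plan` (a final-cell partition
#' of the first tree), the second tree is inserted and the displaced subtree
#' of the first tree is appended at each of its leaves.  Whatever valid plan
#' is chosen, the DD vector of the result equals
#' `dd_convolve(as_ddvector(first), as_ddvector(second))` -- the invariance
#' theorem that justifies working with DD vectors alone.
#'
#' @param first,second explicit trees.
#' @param plan list of vertex paths forming a final-cell partition of
#'   `first`; default appends `second` at every leaf of `first`.
#' @return the concatenated explicit tree.
#' @export
tree_concatenate <- function(first, second, plan = NULL) {
  if (is.null(plan)) plan <- lapply(leaf_paths(first), identity)
  validate_plan(first, plan)
  keys <- vapply(plan, path_key, character(1))
  rec <- function(node, path) {
    if (path_key(path) %in% keys)
      return(append_at_leaves(second, node))
    # valid plans cover every leaf, so 'node' is internal here
    structure(list(rec(node[[1L]], c(path, 1L)),
                   rec(node[[2L]], c(path, 2L))),
              class = "dd_tree_node")
  }
  rec(first, integer(0))
}

leaf_paths <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (is_leaf(node)) {
      out[[length(out) + 1L]] <<- path
    } else {
      walk(node[[1L]], c(path, 1L))
      walk(node[[2L]], c(path, 2L))
    }
  }
  walk(tree, integer(0))
  out
}
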