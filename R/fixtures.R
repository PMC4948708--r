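#' @title Seeded synthetic trees and controlled perturbations
#'
#' @description
#' Every generator here is a pure function of its integer seed: the same
#' call yields byte-identical trees, and the global RNG stream of the
#' caller is left untouched. Topologies come from random sequential leaf
#' attachment (each new leaf subdivides a uniformly chosen edge), which
#' gives unlabelled-shape variety adequate for structural testing; no
#' evolutionary model (birth-death, coalescent, sequence evolution) is
#' implied. Branch lengths, when requested, are exponential with unit
#' mean, a conventional scale-free choice in substitutions/site.
#'
#' @name fixtures
NULL

#' Generate a seeded random binary tree
#'
#' @param n_leaves number of leaves (>= 1); labels are `"T0001"..."Tn"`
#' @param seed integer seed; fully determines the result
#' @param with_lengths draw branch lengths from Exp(1) (otherwise absent)
#' @return a [ctree] with `n_leaves` leaves and, for `n_leaves >= 2`,
#'   exactly `n_leaves - 1` internal nodes
#' @export
random_tree <- function(n_leaves, seed = 1L, with_lengths = FALSE) {
  if (!is_scalar_count(n_leaves)) {
    tree_error("n_leaves must be a positive integer", "structural_error")
  }
  n_leaves <- as.integer(n_leaves)
  labs <- sprintf("T%04d", seq_len(n_leaves))
  withr::with_seed(as.integer(seed), {
    if (n_leaves == 1L) {
      return(seal_tree(0L, list(integer(0)), labs, NA_real_, NA_real_))
    }
    parent <- c(0L, 1L, 1L)
    children <- list(c(2L, 3L), integer(0), integer(0))
    label <- c(NA_character_, labs[1:2])
    for (k in seq_len(n_leaves - 2L) + 2L) {
      # subdivide the edge above a uniformly chosen non-root node
      v <- sample_one(seq_along(parent)[-1L])
      w <- length(parent) + 1L
      lf <- length(parent) + 2L
      pv <- parent[v]
      children[[pv]][match(v, children[[pv]])] <- w
      parent <- c(parent, pv, w)
      parent[v] <- w
      pair <- if (stats::runif(1) < 0.5) c(v, lf) else c(lf, v)
      children[[w]] <- pair
      children[[lf]] <- integer(0)
      label <- c(label, NA_character_, labs[k])
    }
    N <- length(parent)
    elen <- rep(NA_real_, N)
    if (with_lengths) elen[-1L] <- stats::rexp(N - 1L)
    seal_tree(parent, children, label, elen, rep(NA_real_, N))
  })
}

#' Generate a perfectly balanced binary tree
#'
#' Useful for depth/viewport arithmetic with predictable level sizes:
#' every leaf sits at depth `log2(n_leaves)`.
#'
#' @param n_leaves a power of two
#' @return a [ctree]
#' @export
balanced_tree <- function(n_leaves) {
  if (!is_scalar_count(n_leaves) || bitwAnd(n_leaves, n_leaves - 1L) != 0L) {
    tree_error("n_leaves must be a positive power of two", "structural_error")
  }
  n_leaves <- as.integer(n_leaves)
  parent <- integer(0); children <- list(); label <- character(0)
  leaf_count <- 0L
  build <- function(par, size) {
    parent <<- c(parent, par)
    id <- length(parent)
    children[[id]] <<- integer(0)
    if (size == 1L) {
      leaf_count <<- leaf_count + 1L
      label <<- c(label, sprintf("T%04d", leaf_count))
    } else {
      label <<- c(label, NA_character_)
      children[[id]] <<- c(build(id, size %/% 2L), build(id, size %/% 2L))
    }
    id
  }
  build(0L, n_leaves)
  N <- length(parent)
  seal_tree(parent, children, label, rep(NA_real_, N), rep(NA_real_, N))
}

# One nearest-neighbour interchange across a uniformly chosen internal
# (in the unrooted sense) edge. Uses the caller's RNG stream.
nni_once <- function(tree) {
  N <- n_nodes(tree)
  root <- tree$root
  rc <- tree$children[[root]]
  binroot <- length(rc) == 2L
  cand <- which(!tree$is_leaf & seq_len(N) != root & tree$parent != root)
  if (binroot) {
    # the merged root edge, counted once, valid iff both sides internal
    if (all(!tree$is_leaf[rc])) cand <- c(cand, rc[1L])
  } else {
    cand <- c(cand, rc[!tree$is_leaf[rc]])
  }
  if (!length(cand)) {
    tree_error("tree has no internal edge for an NNI move", "structural_error")
  }
  v <- sample_one(cand)
  p <- tree$parent[v]
  other <- if (binroot && p == root) {
    sib <- rc[rc != v]
    tree$children[[sib]]       # quartet partner subtrees across the root edge
  } else {
    tree$children[[p]][tree$children[[p]] != v]
  }
  x <- sample_one(tree$children[[v]])
  y <- sample_one(other)
  px <- tree$parent[x]; py <- tree$parent[y]
  tree$children[[px]][match(x, tree$children[[px]])] <- y
  tree$children[[py]][match(y, tree$children[[py]])] <- x
  tree$parent[x] <- py
  tree$parent[y] <- px
  reseal(tree)
}

#' Apply seeded nearest-neighbour interchanges
#'
#' Each move swaps two subtrees across a uniformly chosen internal edge,
#' so a single move on a binary tree always changes the split set. The
#' leaf label set is never altered.
#'
#' @param tree a [ctree] with >= 4 leaves
#' @param count number of successive moves (0 returns the tree unchanged)
#' @param seed integer seed
#' @return the perturbed [ctree]
#' @export
apply_nni <- function(tree, count, seed = 1L) {
  stopifnot(inherits(tree, "ctree"))
  if (tree$n_leaves < 4L) {
    tree_error("NNI requires at least 4 leaves", "structural_error")
  }
  if (count == 0) return(tree)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(count)) tree <- nni_once(tree)
    tree
  })
}

# Random child-order shuffle at every internal node (caller's RNG stream).
shuffle_children_all <- function(tree) {
  for (v in which(!tree$is_leaf)) {
    k <- length(tree$children[[v]])
    tree$children[[v]] <- tree$children[[v]][sample.int(k)]
  }
  reseal(tree)
}

#' Describe a deterministic tree perturbation
#'
#' @param n_nni number of NNI moves (>= 0)
#' @param reroot reroot on a uniformly chosen edge afterwards
#' @param shuffle_children randomly permute every internal node's children
#' @param seed integer seed; the same plan applied to the same tree always
#'   yields the identical output
#' @return a `perturbation_plan`
#' @export
perturbation_plan <- function(n_nni = 0L, reroot = TRUE,
                              shuffle_children = TRUE, seed = 1L) {
  stopifnot(is.numeric(n_nni), n_nni >= 0)
  structure(list(n_nni = as.integer(n_nni), reroot = isTRUE(reroot),
                 shuffle_children = isTRUE(shuffle_children),
                 seed = as.integer(seed)),
            class = "perturbation_plan")
}

#' Apply a perturbation plan to a tree
#'
#' Applies, in order: NNI moves, an optional random reroot, and optional
#' child-order shuffles, all driven by the plan's single seed. With
#' `n_nni = 0` the unrooted topology (split set) is preserved.
#'
#' @param tree a [ctree]
#' @param plan a [perturbation_plan()]
#' @return the perturbed [ctree]
#' @export
perturb <- function(tree, plan) {
  stopifnot(inherits(tree, "ctree"), inherits(plan, "perturbation_plan"))
  withr::with_seed(plan$seed, {
    if (plan$n_nni > 0L) {
      for (i in seq_len(plan$n_nni)) tree <- nni_once(tree)
    }
    if (plan$reroot && n_nodes(tree) > 1L) {
      tree <- reroot(tree, sample_one(seq_len(n_nodes(tree))[-tree$root]))
    }
    if (plan$shuffle_children) tree <- shuffle_children_all(tree)
    tree
  })
}
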