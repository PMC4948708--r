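# Independent oracles and small utilities shared across the test files.
# These deliberately avoid the package's optimized code paths: label-set
# arithmetic instead of fingerprints, exhaustive enumeration instead of
# heuristics, ape as an outside Newick/topology reference.

labels_below <- function(tree, v) {
  names(tree$leaf_index)[tree$leaves_below[[v]]]
}

# plain set-arithmetic Jaccard on explicit label vectors
jaccard_sets <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

canon <- function(tree) write_newick(tree, include_state = TRUE)

# node whose clade is exactly the given label set (NA if none)
find_node_by_leaves <- function(tree, labs) {
  for (v in seq_len(n_nodes(tree))) {
    if (setequal(labels_below(tree, v), labs)) return(v)
  }
  NA_integer_
}

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# exhaustive minimum of the leaf-order objective over every combination
# of child permutations (feasible for <= ~10 leaves)
brute_best_order_objective <- function(ref, qry) {
  internals <- which(!qry$is_leaf)
  perm_lists <- lapply(internals, function(v) all_perms(length(qry$children[[v]])))
  sizes <- lengths(perm_lists)
  idx <- rep(1L, length(internals))
  best <- Inf
  repeat {
    t2 <- qry
    for (j in seq_along(internals)) {
      v <- internals[j]
      t2$children[[v]] <- qry$children[[v]][perm_lists[[j]][[idx[j]]]]
    }
    t2 <- phylocompare:::reseal(t2)
    best <- min(best, leaf_order_objective(ref, t2))
    j <- 1L
    repeat {
      if (j > length(internals)) return(best)
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
  }
}

# per-candidate-edge aggregate score by literally rerooting and comparing;
# the aggregate is defined over the query (first) tree's internal nodes
naive_rooting_aggregates <- function(ref, qry) {
  cand <- seq_len(n_nodes(qry))[-qry$root]
  vapply(cand, function(x) {
    compare_trees(reroot(qry, x), ref)$aggregate
  }, numeric(1))
}

# seeded random visualization state touching internal nodes only
random_state <- function(tree, seed) {
  withr::with_seed(seed, {
    internals <- which(!tree$is_leaf)
    viz_state(
      collapsed = sample(internals, min(length(internals), 3L)),
      highlighted = sample(seq_len(n_nodes(tree)), 2L),
      viewport = c(800, 480), label_height = 14)
  })
}

# leaf-to-leaf path length matrix through an outside parser (ape)
ape_dists <- function(tree) {
  ph <- ape::read.tree(text = write_newick(tree))
  d <- ape::cophenetic.phylo(ph)
  d[order(rownames(d)), order(colnames(d))]
}
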