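#' @title Comparison-driven layout operations
#'
#' @description
#' Operations that prepare one or two trees for display: automatic
#' best-corresponding rooting (maximize the aggregate BCN score against a
#' reference over all possible root edges), branch-swap leaf ordering
#' (minimize pairwise leaf-order disagreement with the reference via the
#' barycenter heuristic), viewport-driven collapse depth estimation, path
#' expansion to a hidden node, and root-to-leaf search.
#'
#' @name layout_ops
NULL

#' Visualization state of a tree
#'
#' Holds the collapsed and highlighted node sets plus viewport geometry.
#' Collapsed nodes are drawn as triangle stubs and rendering does not
#' descend below them; the visible and hidden node sets always partition
#' the tree's nodes.
#'
#' @param collapsed integer node ids drawn as collapsed stubs
#' @param highlighted integer node ids whose subtrees are highlighted
#' @param viewport drawing area `c(width_px, height_px)`
#' @param label_height vertical pixels consumed by one leaf label row
#' @param selected optional single node id drawn in the selection colour
#' @param search_path optional root-to-leaf node id path to emphasize
#' @return a `viz_state`
#' @export
viz_state <- function(collapsed = integer(0), highlighted = integer(0),
                      viewport = c(960, 600), label_height = 16,
                      selected = NA_integer_, search_path = integer(0)) {
  stopifnot(length(viewport) == 2L, all(viewport > 0), label_height > 0)
  structure(list(collapsed = as.integer(sort(unique(collapsed))),
                 highlighted = as.integer(sort(unique(highlighted))),
                 viewport = as.numeric(viewport),
                 label_height = as.numeric(label_height),
                 selected = as.integer(selected),
                 search_path = as.integer(search_path)),
            class = "viz_state")
}

#' Visible nodes under a visualization state
#'
#' A node is visible when no strict ancestor of it is collapsed; a
#' collapsed node itself is visible (as a stub). `visible_nodes` and
#' [hidden_nodes()] partition the node set.
#'
#' @param tree a [ctree]
#' @param state a [viz_state()]
#' @return integer node ids in drawing (preorder) order
#' @export
visible_nodes <- function(tree, state) {
  coll <- logical(n_nodes(tree))
  coll[state$collapsed] <- TRUE
  out <- integer(0)
  st <- tree$root
  while (length(st)) {
    v <- st[length(st)]
    st <- st[-length(st)]
    out <- c(out, v)
    if (!coll[v]) {
      ch <- tree$children[[v]]
      if (length(ch)) st <- c(st, rev(ch))
    }
  }
  out
}

#' @rdname visible_nodes
#' @export
hidden_nodes <- function(tree, state) {
  setdiff(seq_len(n_nodes(tree)), visible_nodes(tree, state))
}

#' Estimate the deepest collapse depth that fits the viewport
#'
#' Collapsing all internal nodes at depth `d` leaves one display row per
#' leaf at depth <= `d` plus one per collapsed stub. This returns the
#' largest `d >= 1` whose row count times `label_height` fits in the
#' viewport height, so the tree is shown as deep as legibility allows;
#' if even `d = 1` overflows, 1 is returned (the minimum useful depth).
#' The root is at depth 0.
#'
#' @param tree a [ctree]
#' @param state a [viz_state()] supplying viewport and label height
#' @return integer depth >= 1
#' @export
estimate_collapse_depth <- function(tree, state) {
  h <- state$viewport[2]
  lh <- state$label_height
  maxd <- max(tree$depth)
  if (maxd < 1L) return(1L)
  for (d in seq.int(maxd, 1L)) {
    rows <- sum(tree$is_leaf & tree$depth <= d) +
            sum(!tree$is_leaf & tree$depth == d)
    if (rows * lh <= h) return(d)
  }
  1L
}

#' Collapse every internal node at a given depth
#'
#' @param tree a [ctree]
#' @param state a [viz_state()]
#' @param d depth (>= 1) at which internal nodes become collapsed stubs;
#'   depths beyond the tree height yield an empty collapsed set
#' @return the state with its collapsed set replaced
#' @export
collapse_at_depth <- function(tree, state, d) {
  stopifnot(d >= 1)
  state$collapsed <- which(!tree$is_leaf & tree$depth == d)
  state
}

#' Expand the path to a node
#'
#' Removes every collapsed strict ancestor of `target` from the collapsed
#' set, making `target` visible; no other collapsed node is touched.
#'
#' @param tree a [ctree]
#' @param state a [viz_state()]
#' @param target node id to make visible
#' @return the updated state
#' @export
expand_path_to <- function(tree, state, target) {
  target <- check_node(tree, target)
  state$collapsed <- setdiff(state$collapsed, ancestors(tree, target))
  state
}

#' Root-to-leaf search path
#'
#' @param tree a [ctree]
#' @param query_label exact (case-sensitive) leaf label
#' @return integer node ids from the root to the matching leaf, or an
#'   empty vector when the label is absent (absence is not an error)
#' @export
search_leaf <- function(tree, query_label) {
  slot <- tree$leaf_index[query_label]
  if (is.na(slot)) return(integer(0))
  leaf <- tree$leaf_nodes[slot]
  c(rev(ancestors(tree, leaf)), leaf)
}

#' Highlight a node's subtree and its counterpart in the opposing tree
#'
#' Marks the subtree of `node` highlighted (and `node` selected) in
#' `state1`, finds its best corresponding node in `t2` (computing it
#' lazily when `cmp` does not already cover `node`), highlights that
#' node's subtree in `state2`, and expands the path to it so it is
#' visible regardless of the current collapsing.
#'
#' @param t1,t2 trees on the same leaf label set
#' @param cmp a `tree_comparison` from [compare_trees()], possibly
#'   restricted; may be `NULL`
#' @param node node id in `t1`
#' @param state1,state2 the two [viz_state()]s
#' @return list with elements `state1`, `state2`, and the (possibly
#'   extended) `comparison`
#' @export
highlight_subtree <- function(t1, t2, cmp, node, state1, state2) {
  node <- check_node(t1, node)
  if (is.null(cmp)) cmp <- bcn_fast(t1, t2, restrict_to = node)
  cmp <- compare_update(cmp, t1, t2, nodes1 = node)
  m <- cmp$bcn1[node]
  state1$highlighted <- sort(unique(c(state1$highlighted, subtree_nodes(t1, node))))
  state1$selected <- node
  state2$highlighted <- sort(unique(c(state2$highlighted, subtree_nodes(t2, m))))
  state2 <- expand_path_to(t2, state2, m)
  list(state1 = state1, state2 = state2, comparison = cmp)
}

# ---- best rooting -----------------------------------------------------

# Unrooted working copy: a binary root is suppressed so every remaining
# edge is a distinct unrooted edge. Returns the tree plus a map from
# original node ids to working-copy ids (edges above the two old root
# children coincide and map to the same working edge).
unroot_repr <- function(tree) {
  rc <- tree$children[[tree$root]]
  if (length(rc) != 2L || all(tree$is_leaf[rc])) {
    return(list(tree = tree, map = seq_len(n_nodes(tree))))
  }
  keep <- if (!tree$is_leaf[rc[1L]]) rc[1L] else rc[2L]
  other <- setdiff(rc, keep)
  parent <- tree$parent
  children <- tree$children
  elen <- tree$edge_len
  children[[keep]] <- c(children[[keep]], other)
  parent[keep] <- 0L
  parent[other] <- keep
  elen[other] <- na_sum(elen[rc[1L]], elen[rc[2L]])
  elen[keep] <- NA_real_
  old_root <- tree$root
  ids <- seq_len(n_nodes(tree))
  keep_ids <- ids[ids != old_root]
  remap <- integer(n_nodes(tree))
  remap[keep_ids] <- seq_along(keep_ids)
  pk <- parent[keep_ids]
  pk[pk != 0L] <- remap[pk[pk != 0L]]
  ut <- seal_tree(pk,
                  lapply(children[keep_ids], function(x) remap[x]),
                  tree$label[keep_ids], elen[keep_ids], tree$support[keep_ids])
  map <- remap
  map[old_root] <- NA_integer_
  map[rc] <- remap[other]   # both old root edges are the merged edge
  list(tree = ut, map = map)
}

# Aggregate BCN score against `reference` for every candidate rooting of
# `query`, in one precomputation pass. For each clade of the unrooted
# query both the clade itself (s1) and its complement (s2) are scored
# against every reference node; rerooting on any edge re-expresses the
# rooted clade set in terms of these, so per-edge aggregates follow from
# an ancestor walk instead of an explicit reroot + comparison.
rooting_aggregates <- function(reference, query) {
  pr <- align_pair(reference, query)
  tr <- pr$t1
  qr <- pr$t2
  n <- tr$n_leaves
  ur <- unroot_repr(qr)
  U <- ur$tree
  Nu <- n_nodes(U)
  Nr <- n_nodes(tr)
  counts <- numeric(Nr)
  size_r <- tr$clade_size
  parent_r <- tr$parent
  leaf_node_r <- tr$leaf_nodes
  # leaves_below of U are slots in U's own index; map to reference slots
  u2r <- as.integer(tr$leaf_index[names(U$leaf_index)])

  s1 <- rep(NA_real_, Nu)
  s2 <- rep(NA_real_, Nu)
  nonroot <- seq_len(Nu)[-U$root]
  for (v in nonroot) {
    lv <- u2r[U$leaves_below[[v]]]
    for (s in lv) {
      w <- leaf_node_r[s]
      while (w != 0L) {
        counts[w] <- counts[w] + 1
        w <- parent_r[w]
      }
    }
    nA <- length(lv)
    touched <- which(counts > 0)
    s1[v] <- max(counts[touched] / (nA + size_r[touched] - counts[touched]))
    s2[v] <- max((size_r - counts) / (n - nA + counts))
    counts[touched] <- 0
  }

  IN <- which(!U$is_leaf & seq_len(Nu) != U$root)
  S1all <- sum(s1[IN])
  cnt0 <- length(IN)
  agg_u <- rep(NA_real_, Nu)
  for (x in nonroot) {
    s <- S1all
    k <- cnt0
    v <- U$parent[x]
    while (v != U$root) {
      s <- s - s1[v]
      k <- k - 1L
      if (n - U$clade_size[v] >= 2L) { s <- s + s2[v]; k <- k + 1L }
      v <- U$parent[v]
    }
    if (n - U$clade_size[x] >= 2L) { s <- s + s2[x]; k <- k + 1L }
    agg_u[x] <- if (k > 0L) s / k else 1
  }

  # aggregate of the query's current rooting, computed directly
  inr <- internal_nonroot(qr)
  current <- if (length(inr)) {
    d <- bcn_direction_fast(qr, tr, inr)
    mean(d$score[inr])
  } else 1

  cand <- seq_len(n_nodes(query))[-query$root]
  list(candidates = cand,
       aggregate = agg_u[ur$map[cand]],
       current = current)
}

#' Reroot a query tree for maximum consistency with a reference
#'
#' Evaluates every possible root placement (each edge of the query) and
#' returns the query rerooted on the edge maximizing the aggregate BCN
#' score against the reference. Ties go to the edge whose child endpoint
#' has the smallest preorder index; when the current rooting already
#' attains the maximum the query is returned unchanged. The unrooted
#' topology (split set) is never altered.
#'
#' @param reference a [ctree]; the tree being matched against
#' @param query a [ctree] on the same leaf label set
#' @return the rerooted query
#' @examples
#' ref <- parse_newick("((A,B),(C,D));")
#' qry <- parse_newick("(A,(B,(C,D)));")
#' write_newick(best_rooting(ref, qry))
#' @export
best_rooting <- function(reference, query) {
  ra <- rooting_aggregates(reference, query)
  if (!length(ra$candidates) || all(is.na(ra$aggregate))) return(query)
  best <- max(ra$aggregate)
  if (ra$current >= best - 1e-12) return(query)
  ord <- order(query$pre_rank[ra$candidates])
  for (x in ra$candidates[ord]) {
    if (ra$aggregate[match(x, ra$candidates)] >= best - 1e-12) {
      return(reroot(query, x))
    }
  }
  query
}

# ---- leaf order -------------------------------------------------------

#' Pairwise leaf-order disagreement between two trees
#'
#' The number of leaf pairs whose vertical order differs between the two
#' displays (the Kendall tau distance between the query's leaf sequence
#' and the reference's). 0 means the orders agree exactly.
#'
#' @param reference,query trees on the same leaf label set
#' @return non-negative integer count of discordant pairs
#' @export
leaf_order_objective <- function(reference, query) {
  pr <- align_pair(reference, query)  # validates label sets
  rk <- pr$t1$leaf_index[leaf_labels(query)]
  n <- length(rk)
  inv <- 0
  for (i in seq_len(n - 1L)) {
    inv <- inv + sum(rk[(i + 1L):n] < rk[i])
  }
  as.integer(inv)
}

#' Reorder a query tree's children to match a reference leaf order
#'
#' The automated branch-swapping step: children of every internal node
#' are reordered by the barycenter heuristic (ascending mean reference
#' rank of the leaves below each child, ties by preorder index) in one
#' bottom-up pass. The topology (split set) is unchanged, the
#' disagreement objective never increases, and for a query sharing the
#' reference's rooted topology the result attains objective 0.
#'
#' @param reference,query trees on the same leaf label set
#' @return the query with children permuted
#' @export
optimize_leaf_order <- function(reference, query) {
  pr <- align_pair(reference, query)
  rk <- as.numeric(pr$t1$leaf_index)  # reference rank per shared slot
  qr <- pr$t2
  mean_rank <- vapply(qr$leaves_below,
                      function(ix) mean(rk[ix]), numeric(1))
  out <- query
  for (v in which(!qr$is_leaf)) {
    ch <- qr$children[[v]]
    out$children[[v]] <- ch[order(mean_rank[ch], qr$pre_rank[ch])]
  }
  out <- reseal(out)
  if (leaf_order_objective(reference, out) <= leaf_order_objective(reference, query)) {
    out
  } else {
    query
  }
}
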