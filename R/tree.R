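#' @title Rooted phylogenetic trees with leaf-set fingerprints
#'
#' @description
#' A `ctree` is a rooted (possibly multifurcating) tree stored in flat
#' vectors indexed by node id: `parent` (0 for the root), `children`
#' (ordered integer vectors), `label`, `edge_len` (length of the edge
#' *above* each node, `NA` when absent), and `support`. Sealing a tree
#' derives: a preorder numbering, a stable leaf index (bijection
#' label -> slot in `[1, n_leaves]`, in order of first preorder
#' appearance), per-node leaf-set fingerprints as machine-word packed
#' bitsets, node depths, and per-node leaf lists. Fingerprints make the
#' Jaccard leaf-set similarity between any two nodes an O(n/8) byte
#' operation, which is what lets per-node comparison scale to large trees.
#'
#' @name ctree
NULL

# Build a sealed ctree from flat structure vectors. Validates the single-root
# and unique-leaf-label invariants and derives all cached traversal data.
seal_tree <- function(parent, children, label, edge_len, support,
                      state = NULL, node_score = NULL) {
  N <- length(parent)
  stopifnot(length(children) == N, length(label) == N,
            length(edge_len) == N, length(support) == N)
  root <- which(parent == 0L)
  if (length(root) != 1L) {
    tree_error("tree must have exactly one root", "structural_error")
  }
  is_leaf <- lengths(children) == 0L

  # preorder traversal respecting child order
  ord <- integer(N)
  st <- root
  k <- 0L
  while (length(st)) {
    v <- st[length(st)]
    st <- st[-length(st)]
    k <- k + 1L
    ord[k] <- v
    ch <- children[[v]]
    if (length(ch)) st <- c(st, rev(ch))
  }
  if (k != N) tree_error("tree contains unreachable nodes", "structural_error")
  pre_rank <- integer(N)
  pre_rank[ord] <- seq_len(N)

  leaf_ids <- ord[is_leaf[ord]]
  labs <- label[leaf_ids]
  if (anyNA(labs) || any(labs == "")) {
    tree_error("every leaf must carry a non-empty label", "leaf_label_error")
  }
  dup <- unique(labs[duplicated(labs)])
  if (length(dup)) {
    tree_error(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")),
               "duplicate_label_error", labels = dup)
  }
  n_leaves <- length(leaf_ids)
  leaf_index <- stats::setNames(seq_len(n_leaves), labs)

  depth <- integer(N)
  for (v in ord[-1L]) depth[v] <- depth[parent[v]] + 1L

  slot <- integer(N)
  slot[leaf_ids] <- seq_len(n_leaves)
  leaves_below <- vector("list", N)
  for (v in rev(ord)) {
    leaves_below[[v]] <- if (is_leaf[v]) slot[v]
                         else unlist(leaves_below[children[[v]]], use.names = FALSE)
  }
  fp <- lapply(leaves_below, fp_build, n_leaves = n_leaves)

  structure(list(
    parent = as.integer(parent), children = children,
    label = as.character(label), edge_len = as.numeric(edge_len),
    support = as.numeric(support),
    root = root, n_leaves = n_leaves,
    is_leaf = is_leaf, preorder = ord, pre_rank = pre_rank,
    depth = depth, leaf_index = leaf_index, leaf_nodes = leaf_ids,
    leaves_below = leaves_below, clade_size = lengths(leaves_below),
    fingerprint = fp,
    state = state, node_score = node_score
  ), class = "ctree")
}

# Recompute derived fields after in-place structural edits (same node ids).
reseal <- function(tree) {
  seal_tree(tree$parent, tree$children, tree$label, tree$edge_len,
            tree$support, state = tree$state, node_score = tree$node_score)
}

#' Number of nodes in a tree
#' @param tree a `ctree`
#' @return integer node count (leaves plus internal nodes)
#' @export
n_nodes <- function(tree) length(tree$parent)

#' Leaf labels in display (preorder) order
#' @param tree a `ctree`
#' @return character vector of length `tree$n_leaves`
#' @export
leaf_labels <- function(tree) names(tree$leaf_index)

#' Find a node by its label
#' @param tree a `ctree`
#' @param label exact label (leaf or internal), case-sensitive
#' @return node id, or `NA` if absent
#' @export
find_node <- function(tree, label) {
  hit <- which(!is.na(tree$label) & tree$label == label)
  if (length(hit)) hit[1L] else NA_integer_
}

#' All nodes of the subtree rooted at a node
#' @param tree a `ctree`
#' @param node node id
#' @return integer node ids in preorder, starting with `node`
#' @export
subtree_nodes <- function(tree, node) {
  check_node(tree, node)
  out <- integer(0)
  st <- as.integer(node)
  while (length(st)) {
    v <- st[length(st)]
    st <- st[-length(st)]
    out <- c(out, v)
    ch <- tree$children[[v]]
    if (length(ch)) st <- c(st, rev(ch))
  }
  out
}

# Strict ancestors of a node, closest first.
ancestors <- function(tree, node) {
  out <- integer(0)
  v <- tree$parent[node]
  while (v != 0L) {
    out <- c(out, v)
    v <- tree$parent[v]
  }
  out
}

check_node <- function(tree, node) {
  if (!is.numeric(node) || length(node) != 1L || is.na(node) ||
      node < 1L || node > n_nodes(tree) || node != as.integer(node)) {
    tree_error("node id is not in the tree", "structural_error")
  }
  invisible(as.integer(node))
}

#' Recompute leaf-set fingerprints, optionally under a foreign leaf index
#'
#' Re-derives every node's fingerprint (and leaf list) so that bit *i*
#' corresponds to slot *i* of `leaf_index`. Used to align two trees on a
#' shared index before computing similarities. With the default index this
#' is a no-op re-derivation satisfying the union invariant.
#'
#' @param tree a `ctree`
#' @param leaf_index named integer bijection label -> slot; must cover
#'   exactly the tree's leaf labels
#' @return the tree with fingerprints (and `leaf_index`) rebuilt
#' @export
compute_fingerprints <- function(tree, leaf_index = tree$leaf_index) {
  own <- names(tree$leaf_index)
  if (length(leaf_index) != tree$n_leaves || !setequal(names(leaf_index), own)) {
    tree_error("leaf_index does not cover exactly this tree's leaves",
               "leafset_mismatch_error")
  }
  new_slot <- as.integer(leaf_index[own])  # old slot j -> new slot
  tree$leaves_below <- lapply(tree$leaves_below, function(ix) new_slot[ix])
  tree$fingerprint <- lapply(tree$leaves_below, fp_build, n_leaves = tree$n_leaves)
  ln <- integer(tree$n_leaves)
  ln[new_slot] <- tree$leaf_nodes
  tree$leaf_nodes <- ln
  labs_by_slot <- character(tree$n_leaves)
  labs_by_slot[as.integer(leaf_index)] <- names(leaf_index)
  tree$leaf_index <- stats::setNames(seq_len(tree$n_leaves), labs_by_slot)
  tree
}

#' Reroot a tree on the edge above a node
#'
#' Places a new root on the edge between `node` and its parent. When the
#' edge has a branch length the new root sits at its midpoint (half the
#' length on each side), preserving all leaf-to-leaf path lengths;
#' otherwise both halves are recorded as absent. The old root, if left
#' with a single child, is suppressed and its two incident branch lengths
#' summed. The multiset of non-trivial splits is unchanged. Node ids of
#' the result are renumbered; any attached visualization state is dropped.
#'
#' @param tree a `ctree`
#' @param node id of the child endpoint of the edge to root on (must not
#'   be the root)
#' @return a new `ctree`
#' @export
reroot <- function(tree, node) {
  node <- check_node(tree, node)
  if (node == tree$root) {
    tree_error("cannot reroot on the root: it has no parent edge",
               "structural_error")
  }
  N <- n_nodes(tree)
  par <- tree$parent
  ch <- tree$children
  elen <- tree$edge_len
  supp <- tree$support

  R <- N + 1L
  np <- integer(R)
  nch <- vector("list", R)
  nlen <- rep(NA_real_, R)
  nsupp <- rep(NA_real_, R)
  nlab <- c(tree$label, NA_character_)

  p <- par[node]
  half <- elen[node] / 2
  nch[[R]] <- c(node, p)
  np[c(node, p)] <- R
  nlen[c(node, p)] <- half
  nsupp[c(node, p)] <- supp[node]

  # Orient all remaining edges away from the new root. rf[v] is the
  # original-graph neighbour v was reached from.
  rf <- integer(N)
  rf[node] <- p
  rf[p] <- node
  queue <- c(node, p)
  qi <- 1L
  while (qi <= length(queue)) {
    v <- queue[qi]
    qi <- qi + 1L
    nbr <- ch[[v]]
    if (par[v] != 0L) nbr <- c(nbr, par[v])
    nbr <- nbr[nbr != rf[v]]
    nch[[v]] <- nbr
    for (w in nbr) {
      np[w] <- v
      rf[w] <- v
      e <- if (par[w] == v) w else v  # original child endpoint of edge v-w
      nlen[w] <- elen[e]
      nsupp[w] <- supp[e]
      queue <- c(queue, w)
    }
  }

  # Suppress the old root if it ended up with a single child.
  drop <- logical(R)
  v <- tree$root
  if (length(nch[[v]]) == 1L) {
    child <- nch[[v]][1L]
    pv <- np[v]
    nch[[pv]][match(v, nch[[pv]])] <- child
    np[child] <- pv
    nlen[child] <- na_sum(nlen[v], nlen[child])
    if (is.na(nsupp[child])) nsupp[child] <- nsupp[v]
    drop[v] <- TRUE
  }

  keep <- which(!drop)
  remap <- integer(R)
  remap[keep] <- seq_along(keep)
  np2 <- ifelse(np[keep] == 0L, 0L, remap[np[keep]])
  nch2 <- lapply(nch[keep], function(x) remap[x])
  seal_tree(np2, nch2, nlab[keep], nlen[keep], nsupp[keep])
}

#' Permute the children of a node
#'
#' Reorders the child list of `node` according to `permutation`. This is a
#' pure display operation: the split set, fingerprints, and all leaf-set
#' similarities are unchanged; only the leaf ordering (and hence preorder
#' numbering) moves.
#'
#' @param tree a `ctree`
#' @param node node id
#' @param permutation a permutation of `seq_along(children)`
#' @return a new `ctree` with the same node ids
#' @export
swap_children <- function(tree, node, permutation) {
  node <- check_node(tree, node)
  ch <- tree$children[[node]]
  k <- length(ch)
  if (length(permutation) != k || !setequal(permutation, seq_len(k))) {
    tree_error("permutation must be a permutation of the node's children",
               "structural_error")
  }
  tree$children[[node]] <- ch[permutation]
  reseal(tree)
}

#' Non-trivial splits (bipartitions) of a tree
#'
#' One canonical split per internal edge, each encoded as a hex string
#' over the leaf index with the side *not* containing leaf slot 1
#' (canonicalized by complementing when needed). Two trees on the same
#' leaf index have the same unrooted topology iff their split sets are
#' equal. Trivial splits (one side a single leaf) are excluded; a star
#' tree yields an empty set.
#'
#' @param tree a `ctree`
#' @param leaf_index optional shared leaf index (see
#'   [compute_fingerprints()]) so splits of two trees are comparable
#' @return sorted character vector of canonical split keys
#' @export
tree_splits <- function(tree, leaf_index = tree$leaf_index) {
  tree <- compute_fingerprints(tree, leaf_index)
  n <- tree$n_leaves
  full <- fp_build(seq_len(n), n)
  keys <- character(0)
  for (v in seq_len(n_nodes(tree))) {
    if (v == tree$root) next
    k <- tree$clade_size[v]
    if (k < 2L || k > n - 2L) next
    fp <- tree$fingerprint[[v]]
    if (as.logical(rawToBits(fp)[1L])) fp <- full & !fp
    keys <- c(keys, fp_key(fp))
  }
  sort(unique(keys))
}

#' @export
print.ctree <- function(x, ...) {
  cat(sprintf("Phylogenetic tree: %d leaves, %d nodes, depth %d\n",
              x$n_leaves, n_nodes(x), max(x$depth)))
  nw <- write_newick(x)
  if (nchar(nw) > 70) nw <- paste0(substr(nw, 1, 67), "...")
  cat(" ", nw, "\n")
  if (!is.null(x$state)) {
    cat(sprintf("  state: %d collapsed, %d highlighted\n",
                length(x$state$collapsed), length(x$state$highlighted)))
  }
  invisible(x)
}
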