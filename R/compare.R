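#' @title Per-node similarity and best-corresponding-node mapping
#'
#' @description
#' For two trees on the same leaf set, the similarity between a node `a`
#' of one tree and a node `b` of the other is the Jaccard index of the
#' leaf sets below them, `S(a,b) = |L(a) n L(b)| / |L(a) u L(b)|`. The
#' best corresponding node (BCN) of `a` is the node of the opposing tree
#' maximizing `S`, and its score drives the colour coding of a
#' side-by-side display. Two routes are provided: [bcn_oracle()] pairs
#' every node with every node via explicit 0/1 membership matrices
#' (O(n^2), the correctness reference), while [bcn_fast()] climbs from
#' the shared leaves and visits, for each query node, only the opposing
#' nodes that are ancestors of its leaves, accumulating intersection
#' sizes in one pass; with bitset fingerprints this is what makes
#' whole-tree comparison fast. Ties in the argmax are broken
#' deterministically: larger intersection first, then smaller candidate
#' leaf set, then smaller preorder index.
#'
#' @name comparison
NULL

# Verify identical leaf label sets and re-express t2's fingerprints and
# leaf lists in t1's leaf index so set arithmetic is bit-compatible.
align_pair <- function(t1, t2) {
  l1 <- names(t1$leaf_index)
  l2 <- names(t2$leaf_index)
  if (!setequal(l1, l2) || t1$n_leaves != t2$n_leaves) {
    only1 <- setdiff(l1, l2)
    only2 <- setdiff(l2, l1)
    tree_error(paste0(
      "trees must share an identical leaf label set; only in tree 1: [",
      paste(only1, collapse = ", "), "]; only in tree 2: [",
      paste(only2, collapse = ", "), "]"),
      "leafset_mismatch_error", only1 = only1, only2 = only2)
  }
  if (identical(t1$leaf_index, t2$leaf_index)) return(list(t1 = t1, t2 = t2))
  list(t1 = t1, t2 = compute_fingerprints(t2, t1$leaf_index))
}

#' Jaccard leaf-set similarity between two nodes
#'
#' @param t1,t2 trees on the same leaf label set (a tree may be compared
#'   with itself)
#' @param a node id in `t1`
#' @param b node id in `t2`
#' @return `|L(a) n L(b)| / |L(a) u L(b)|`, in `[0, 1]`; symmetric; equal
#'   to 1 iff the two leaf sets are identical
#' @export
node_similarity <- function(t1, a, t2, b) {
  a <- check_node(t1, a)
  b <- check_node(t2, b)
  pr <- align_pair(t1, t2)
  fa <- pr$t1$fingerprint[[a]]
  fb <- pr$t2$fingerprint[[b]]
  i <- fp_count(fa & fb)
  u <- pr$t1$clade_size[a] + pr$t2$clade_size[b] - i
  i / u
}

# Deterministic argmax with exact rational comparison. i, u are integer
# valued; candidates first screened by a float window, then compared via
# cross-multiplication (exact in doubles at these magnitudes). Ties:
# larger i, then smaller candidate clade size, then smaller preorder rank.
pick_bcn <- function(i, u, size, pre) {
  sim <- i / u
  cand <- which(sim >= max(sim) - 1e-9)
  b <- cand[1L]
  for (k in cand[-1L]) {
    d <- i[k] * u[b] - i[b] * u[k]
    if (d > 0 ||
        (d == 0 && (i[k] > i[b] ||
          (i[k] == i[b] && (size[k] < size[b] ||
            (size[k] == size[b] && pre[k] < pre[b])))))) {
      b <- k
    }
  }
  b
}

# Fast one-direction BCN: for each query node climb the reference tree
# from the leaves of its clade, counting hits per reference node.
bcn_direction_fast <- function(tq, tr, nodes) {
  Nr <- n_nodes(tr)
  counts <- numeric(Nr)
  parent_r <- tr$parent
  leaf_node_r <- tr$leaf_nodes
  size_r <- tr$clade_size
  pre_r <- tr$pre_rank
  score <- rep(NA_real_, n_nodes(tq))
  bcn <- rep(NA_integer_, n_nodes(tq))
  for (nq in nodes) {
    lv <- tq$leaves_below[[nq]]
    for (s in lv) {
      v <- leaf_node_r[s]
      while (v != 0L) {
        counts[v] <- counts[v] + 1
        v <- parent_r[v]
      }
    }
    touched <- which(counts > 0)
    i <- counts[touched]
    u <- length(lv) + size_r[touched] - i
    b <- pick_bcn(i, u, size_r[touched], pre_r[touched])
    score[nq] <- i[b] / u[b]
    bcn[nq] <- touched[b]
    counts[touched] <- 0
  }
  list(score = score, bcn = bcn, n_computed = length(nodes))
}

# Exhaustive one-direction BCN over explicit 0/1 membership matrices.
# Independent of the fingerprint machinery by construction.
bcn_direction_oracle <- function(tq, tr) {
  n <- tq$n_leaves
  Mq <- matrix(0, n_nodes(tq), n)
  for (v in seq_len(n_nodes(tq))) Mq[v, tq$leaves_below[[v]]] <- 1
  Mr <- matrix(0, n_nodes(tr), n)
  for (v in seq_len(n_nodes(tr))) Mr[v, tr$leaves_below[[v]]] <- 1
  I <- Mq %*% t(Mr)
  U <- outer(tq$clade_size, tr$clade_size, `+`) - I
  score <- numeric(n_nodes(tq))
  bcn <- integer(n_nodes(tq))
  for (v in seq_len(n_nodes(tq))) {
    b <- pick_bcn(I[v, ], U[v, ], tr$clade_size, tr$pre_rank)
    score[v] <- I[v, b] / U[v, b]
    bcn[v] <- b
  }
  list(score = score, bcn = bcn, n_computed = n_nodes(tq))
}

internal_nonroot <- function(tree) {
  which(!tree$is_leaf & seq_len(n_nodes(tree)) != tree$root)
}

make_comparison <- function(t1, t2, d1, d2, method) {
  inr <- internal_nonroot(t1)
  agg <- if (length(inr) && !anyNA(d1$score[inr])) {
    mean(d1$score[inr])
  } else if (!length(inr) && !anyNA(d1$score)) {
    mean(d1$score[-t1$root])        # degenerate trees: leaves only
  } else NA_real_
  structure(list(
    score1 = d1$score, bcn1 = d1$bcn,
    score2 = d2$score, bcn2 = d2$bcn,
    aggregate = agg,
    n_computed = d1$n_computed + d2$n_computed,
    method = method
  ), class = "tree_comparison")
}

#' Compare two trees node by node
#'
#' Computes per-node similarity scores and BCN mappings in both
#' directions, plus an aggregate score: the mean BCN score over the
#' internal non-root nodes of the first tree (the root is excluded since
#' its leaf set is always the full taxon set; for trees without internal
#' non-root nodes the mean is over the leaves). The aggregate is the
#' objective maximized by [best_rooting()].
#'
#' @param t1,t2 trees on the same leaf label set
#' @param method `"fast"` (leaf-climbing search) or `"oracle"`
#'   (exhaustive all-pairs reference implementation); both produce
#'   identical scores and mappings
#' @param restrict1,restrict2 optional node ids to compute (lazy
#'   evaluation: only the requested nodes are scored, the aggregate is
#'   `NA`); `"fast"` only
#' @return a `tree_comparison` with `score1`, `bcn1` (per node of `t1`,
#'   ids into `t2`), `score2`, `bcn2`, `aggregate`, and `n_computed`
#' @examples
#' t1 <- parse_newick("((A,B),(C,D));")
#' t2 <- parse_newick("((A,C),(B,D));")
#' compare_trees(t1, t2)$aggregate
#' @export
compare_trees <- function(t1, t2, method = c("fast", "oracle"),
                          restrict1 = NULL, restrict2 = NULL) {
  method <- match.arg(method)
  pr <- align_pair(t1, t2)
  if (method == "oracle") {
    if (!is.null(restrict1) || !is.null(restrict2)) {
      tree_error("restriction is only supported by the fast method",
                 "structural_error")
    }
    d1 <- bcn_direction_oracle(pr$t1, pr$t2)
    d2 <- bcn_direction_oracle(pr$t2, pr$t1)
  } else {
    n1 <- if (is.null(restrict1)) seq_len(n_nodes(t1)) else as.integer(restrict1)
    n2 <- if (is.null(restrict2)) seq_len(n_nodes(t2)) else as.integer(restrict2)
    d1 <- bcn_direction_fast(pr$t1, pr$t2, n1)
    d2 <- bcn_direction_fast(pr$t2, pr$t1, n2)
  }
  make_comparison(pr$t1, pr$t2, d1, d2, method)
}

#' @rdname compare_trees
#' @param restrict_to optional node ids of `t1` to score (lazy contract)
#' @export
bcn_fast <- function(t1, t2, restrict_to = NULL) {
  compare_trees(t1, t2, method = "fast", restrict1 = restrict_to,
                restrict2 = if (is.null(restrict_to)) NULL else integer(0))
}

#' @rdname compare_trees
#' @export
bcn_oracle <- function(t1, t2) {
  compare_trees(t1, t2, method = "oracle")
}

# Fill in missing (lazily skipped) scores for the given nodes in place.
compare_update <- function(cmp, t1, t2, nodes1 = integer(0), nodes2 = integer(0)) {
  pr <- align_pair(t1, t2)
  miss1 <- nodes1[is.na(cmp$score1[nodes1])]
  miss2 <- nodes2[is.na(cmp$score2[nodes2])]
  if (length(miss1)) {
    d <- bcn_direction_fast(pr$t1, pr$t2, miss1)
    cmp$score1[miss1] <- d$score[miss1]
    cmp$bcn1[miss1] <- d$bcn[miss1]
    cmp$n_computed <- cmp$n_computed + length(miss1)
  }
  if (length(miss2)) {
    d <- bcn_direction_fast(pr$t2, pr$t1, miss2)
    cmp$score2[miss2] <- d$score[miss2]
    cmp$bcn2[miss2] <- d$bcn[miss2]
    cmp$n_computed <- cmp$n_computed + length(miss2)
  }
  cmp
}

#' @export
print.tree_comparison <- function(x, ...) {
  done1 <- sum(!is.na(x$score1))
  cat(sprintf("Tree comparison (%s): %d + %d node scores computed\n",
              x$method, done1, sum(!is.na(x$score2))))
  if (!is.na(x$aggregate)) {
    cat(sprintf("  aggregate BCN score: %.6f\n", x$aggregate))
  }
  invisible(x)
}
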