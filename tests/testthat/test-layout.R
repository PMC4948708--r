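test_that("best_rooting recovers the reference rooting", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_identical(write_newick(best_rooting(tr, tr)), write_newick(tr))

  qry <- parse_newick("(A,(B,(C,D)));")
  br <- best_rooting(tr, qry)
  expect_equal(compare_trees(tr, br)$aggregate, 1)
  expect_identical(tree_splits(br, tr$leaf_index), tree_splits(tr))

  t3 <- parse_newick("((A,B),(C,E));")
  expect_error(best_rooting(tr, t3), class = "leafset_mismatch_error")
})

test_that("per-edge aggregates match explicit reroot-and-compare", {
  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(5:16, 1))
    ref <- random_tree(n, seed = seed)
    qry <- perturb(ref, perturbation_plan(seed %% 3, TRUE, TRUE, seed + 300L))
    ra <- phylocompare:::rooting_aggregates(ref, qry)
    expect_equal(ra$aggregate, naive_rooting_aggregates(ref, qry), tolerance = 1e-12)
    expect_equal(ra$current, compare_trees(qry, ref)$aggregate)
  }
})

test_that("best_rooting attains aggregate 1 on rerooted copies and keeps splits", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(6:64, 1))
    tr <- random_tree(n, seed = seed, with_lengths = TRUE)
    qry <- perturb(tr, perturbation_plan(0, TRUE, TRUE, seed + 400L))
    br <- best_rooting(tr, qry)
    expect_equal(compare_trees(tr, br)$aggregate, 1)
    expect_identical(tree_splits(br, tr$leaf_index), tree_splits(tr))
  }
})

test_that("leaf-order optimization reaches the exhaustive optimum", {
  ref <- parse_newick("((A,B),(C,D));")
  qry <- parse_newick("((C,D),(B,A));")
  opt <- optimize_leaf_order(ref, qry)
  expect_identical(leaf_labels(opt), c("A", "B", "C", "D"))
  expect_equal(leaf_order_objective(ref, opt), 0L)

  # already ordered -> unchanged
  expect_identical(write_newick(optimize_leaf_order(ref, ref)), write_newick(ref))

  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(5:10, 1))
    ref <- random_tree(n, seed = seed)
    qry <- perturb(ref, perturbation_plan(0, FALSE, TRUE, seed + 600L))
    opt <- optimize_leaf_order(ref, qry)
    obj <- leaf_order_objective(ref, opt)
    expect_lte(obj, leaf_order_objective(ref, qry))   # never increases
    expect_equal(obj, brute_best_order_objective(ref, qry))
    expect_equal(obj, 0L)                             # same-topology optimum
    expect_identical(tree_splits(opt, ref$leaf_index), tree_splits(qry, ref$leaf_index))
  }
})

test_that("collapse depth estimation fits the viewport rule", {
  tr <- parse_newick("((A,B),(C,D));")
  st <- viz_state(viewport = c(800, 800), label_height = 16)
  expect_equal(estimate_collapse_depth(tr, st), max(tr$depth))  # no collapsing

  big <- balanced_tree(1024)
  st <- viz_state(viewport = c(800, 640), label_height = 16)
  expect_equal(estimate_collapse_depth(big, st), 5L)  # 32 stubs fit, 64 do not

  tiny <- viz_state(viewport = c(100, 10), label_height = 16)
  expect_equal(estimate_collapse_depth(big, tiny), 1L)

  # returned depth always satisfies the fitting rule (or is the floor 1)
  for (seed in 1:6) {
    tr <- random_tree(withr::with_seed(seed, sample(8:200, 1)), seed = seed)
    for (h in c(64, 320, 4000)) {
      st <- viz_state(viewport = c(800, h), label_height = 16)
      d <- estimate_collapse_depth(tr, st)
      rows <- sum(tr$is_leaf & tr$depth <= d) + sum(!tr$is_leaf & tr$depth == d)
      expect_true(d == 1L || rows * 16 <= h)
      if (d < max(tr$depth)) {
        rows_next <- sum(tr$is_leaf & tr$depth <= d + 1L) +
                     sum(!tr$is_leaf & tr$depth == d + 1L)
        expect_gt(rows_next * 16, h)
      }
    }
  }
})

test_that("collapse and expand keep visible/hidden a partition", {
  tr <- parse_newick("((A,B),(C,D));")
  st <- collapse_at_depth(tr, viz_state(), 1)
  expect_setequal(st$collapsed, which(!tr$is_leaf & tr$depth == 1))
  vis <- visible_nodes(tr, st)
  expect_length(vis, 3L)                       # root + two stubs
  expect_false(any(tr$is_leaf[vis]))
  expect_setequal(c(vis, hidden_nodes(tr, st)), seq_len(n_nodes(tr)))

  expect_length(collapse_at_depth(tr, viz_state(), 99)$collapsed, 0L)

  for (seed in 1:6) {
    tr <- random_tree(withr::with_seed(seed, sample(5:80, 1)), seed = seed)
    for (d in 1:4) {
      st <- collapse_at_depth(tr, viz_state(), d)
      expect_setequal(c(visible_nodes(tr, st), hidden_nodes(tr, st)),
                      seq_len(n_nodes(tr)))
    }
  }
})

test_that("expand_path_to expands exactly the collapsed ancestors", {
  tr <- random_tree(64, seed = 20)
  st <- collapse_at_depth(tr, viz_state(), 1)
  leaf <- tr$leaf_nodes[40]
  st2 <- expand_path_to(tr, st, leaf)
  expect_true(leaf %in% visible_nodes(tr, st2))
  anc <- phylocompare:::ancestors(tr, leaf)
  expect_setequal(setdiff(st$collapsed, st2$collapsed), intersect(st$collapsed, anc))

  # already-visible target leaves the state unchanged
  vis <- visible_nodes(tr, st)
  expect_identical(expand_path_to(tr, st, vis[1]), st)
  expect_error(expand_path_to(tr, st, 10000), class = "structural_error")
})

test_that("search_leaf returns the root-to-leaf path", {
  tr <- parse_newick("((A,B),(C,D));")
  path <- search_leaf(tr, "C")
  expect_equal(path[1], tr$root)
  expect_equal(tr$label[path[length(path)]], "C")
  expect_setequal(labels_below(tr, path[2]), c("C", "D"))
  expect_length(search_leaf(tr, "Z"), 0L)

  tr <- random_tree(50, seed = 8)
  for (lab in leaf_labels(tr)) {
    path <- search_leaf(tr, lab)
    expect_equal(path[1], tr$root)
    expect_equal(tr$label[path[length(path)]], lab)
    expect_identical(path[-length(path)],
                     rev(phylocompare:::ancestors(tr, path[length(path)])))
  }
})

test_that("highlight_subtree marks both trees and reveals the counterpart", {
  t1 <- parse_newick("((A,B),(C,D));")
  ab <- find_node_by_leaves(t1, c("A", "B"))
  hs <- highlight_subtree(t1, t1, NULL, ab, viz_state(), viz_state())
  expect_setequal(hs$state1$highlighted, subtree_nodes(t1, ab))
  expect_setequal(hs$state2$highlighted, subtree_nodes(t1, ab))
  expect_equal(hs$state1$selected, ab)

  # BCN inside a collapsed subtree becomes visible
  tr <- random_tree(64, seed = 31)
  qry <- perturb(tr, perturbation_plan(0, TRUE, TRUE, seed = 32))
  s2 <- collapse_at_depth(qry, viz_state(), 1)
  deep <- which(tr$depth > 2 & !tr$is_leaf)[1]
  hs <- highlight_subtree(tr, qry, NULL, deep, viz_state(), s2)
  bcn <- hs$comparison$bcn1[deep]
  expect_true(bcn %in% visible_nodes(qry, hs$state2))

  # highlighting a leaf highlights the namesake leaf opposite
  hs <- highlight_subtree(t1, t1, NULL, find_node(t1, "D"), viz_state(), viz_state())
  expect_equal(hs$state2$highlighted, find_node(t1, "D"))
  expect_error(highlight_subtree(t1, t1, NULL, 99, viz_state(), viz_state()),
               class = "structural_error")
})
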