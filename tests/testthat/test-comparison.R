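test_that("node similarity is the Jaccard index of the leaf sets", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,B,C),D);")
  ab1 <- find_node_by_leaves(t1, c("A", "B"))
  expect_equal(node_similarity(t1, ab1, t1, ab1), 1)
  cd1 <- find_node_by_leaves(t1, c("C", "D"))
  expect_equal(node_similarity(t1, ab1, t1, cd1), 0)
  abc2 <- find_node_by_leaves(t2, c("A", "B", "C"))
  expect_equal(node_similarity(t1, ab1, t2, abc2), 2 / 3)
  # symmetry on the same pair
  expect_equal(node_similarity(t2, abc2, t1, ab1), 2 / 3)

  t3 <- parse_newick("((A,B),(C,E));")
  expect_error(node_similarity(t1, 1, t3, 1), class = "leafset_mismatch_error")
})

test_that("similarity equals set-arithmetic Jaccard on random node pairs", {
  for (seed in 1:10) {
    t1 <- random_tree(24, seed = seed)
    t2 <- perturb(t1, perturbation_plan(3, TRUE, TRUE, seed = seed + 100L))
    pairs <- withr::with_seed(seed, cbind(sample(n_nodes(t1), 30, TRUE),
                                          sample(n_nodes(t2), 30, TRUE)))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      la <- labels_below(t1, a); lb <- labels_below(t2, b)
      expect_equal(node_similarity(t1, a, t2, b), jaccard_sets(la, lb))
      expect_equal(node_similarity(t1, a, t2, b) == 1, setequal(la, lb))
    }
  }
})

test_that("the oracle applies the documented tie-break", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  cmp <- bcn_oracle(t1, t2)
  ab <- find_node_by_leaves(t1, c("A", "B"))
  # {A,B} ties at 0.5 with leaves A, B and the root; larger intersection wins
  expect_equal(cmp$bcn1[ab], t2$root)
  expect_equal(cmp$score1[ab], 0.5)
  # leaves map to their namesakes with score 1
  for (lab in c("A", "B", "C", "D")) {
    v <- find_node(t1, lab)
    expect_equal(cmp$score1[v], 1)
    expect_equal(t2$label[cmp$bcn1[v]], lab)
  }
})

test_that("self-comparison scores 1 everywhere", {
  tr <- random_tree(40, seed = 2)
  for (cmp in list(bcn_oracle(tr, tr), bcn_fast(tr, tr))) {
    expect_true(all(cmp$score1 == 1) && all(cmp$score2 == 1))
    expect_equal(cmp$aggregate, 1)
    expect_equal(cmp$bcn1, seq_len(n_nodes(tr)))  # identity mapping
  }
})

test_that("fast search agrees with the oracle on scores and mappings", {
  for (seed in 1:25) {
    n <- withr::with_seed(seed, sample(4:40, 1))
    t1 <- random_tree(n, seed = seed)
    t2 <- if (seed %% 2) random_tree(n, seed = seed + 999L)
          else perturb(t1, perturbation_plan(seed %% 5, TRUE, TRUE, seed + 999L))
    fast <- bcn_fast(t1, t2)
    slow <- bcn_oracle(t1, t2)
    expect_equal(fast$score1, slow$score1)
    expect_identical(fast$bcn1, slow$bcn1)
    expect_equal(fast$score2, slow$score2)
    expect_identical(fast$bcn2, slow$bcn2)
    expect_true(all(fast$score1 >= 0 & fast$score1 <= 1))
    # score(n) == similarity(n, bcn(n))
    probe <- withr::with_seed(seed, sample(n_nodes(t1), 3))
    for (v in probe) {
      expect_equal(fast$score1[v], node_similarity(t1, v, t2, fast$bcn1[v]))
    }
  }
})

test_that("restriction computes exactly the requested nodes", {
  tr <- random_tree(16, seed = 6)
  cmp <- bcn_fast(tr, tr, restrict_to = tr$root)
  expect_equal(cmp$n_computed, 1L)
  expect_equal(cmp$score1[tr$root], 1)
  expect_equal(sum(!is.na(cmp$score1)), 1L)
  expect_true(all(is.na(cmp$score2)))
  expect_true(is.na(cmp$aggregate))

  # lazy fill-in touches only what is missing
  cmp2 <- phylocompare:::compare_update(cmp, tr, tr,
                                        nodes1 = c(tr$root, 2L), nodes2 = 2L)
  expect_equal(cmp2$n_computed, 3L)
  expect_equal(cmp2$score1[2L], 1)
  expect_error(compare_trees(tr, tr, method = "oracle", restrict1 = 1L),
               class = "structural_error")
})

test_that("rerooted copies retain perfect clade matches", {
  for (seed in 1:5) {
    tr <- random_tree(12, seed = seed)
    rr <- perturb(tr, perturbation_plan(0, TRUE, FALSE, seed + 50L))
    cmp <- bcn_fast(tr, rr)
    oracle <- bcn_oracle(tr, rr)
    expect_equal(cmp$score1, oracle$score1)
    # every clade of tr present in the rerooted orientation scores 1
    rr_clades <- vapply(seq_len(n_nodes(rr)),
                        function(v) paste(sort(labels_below(rr, v)), collapse = "|"), "")
    for (v in seq_len(n_nodes(tr))) {
      key <- paste(sort(labels_below(tr, v)), collapse = "|")
      if (key %in% rr_clades) expect_equal(cmp$score1[v], 1)
    }
  }
})

test_that("median aggregate degrades monotonically with NNI count", {
  ks <- c(1, 2, 4, 8)
  med <- vapply(ks, function(k) {
    stats::median(vapply(1:10, function(s) {
      tr <- random_tree(48, seed = s)
      compare_trees(tr, apply_nni(tr, k, seed = s + 7000L))$aggregate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})
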