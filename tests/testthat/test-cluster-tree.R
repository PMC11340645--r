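test_that("cosine similarity graph matches hand-computed cosines", {
  m <- toy_counts(rbind(c(1, 1), c(1, 0), c(0, 2), c(2, 2)))
  g <- cosine_similarity_graph(m)
  w <- g$weights
  expect_equal(w["c1", "c4"], 1, tolerance = 1e-12)          # identical direction
  expect_equal(w["c2", "c3"], 0, tolerance = 1e-12)          # orthogonal
  expect_equal(w["c1", "c2"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(diag(w), rep(0, 4), ignore_attr = TRUE)
  expect_equal(w, t(w))
  expect_equal(g$total_weight, sum(w))
  expect_error(cosine_similarity_graph(toy_counts(rbind(c(1, 1), c(0, 0)))),
    "zero norm")
})

test_that("modularity is 0 for one community and 0.5 for split triangles", {
  g <- two_triangles()
  expect_identical(newman_girvan_modularity(g, rep(1, 6)), 0)
  expect_equal(newman_girvan_modularity(g, c(1, 1, 1, 2, 2, 2)), 0.5)
  # moving one vertex across strictly lowers Q
  expect_lt(newman_girvan_modularity(g, c(1, 1, 2, 2, 2, 2)), 0.5)
  # random graphs: single community is exactly 0
  set.seed(4)
  for (k in 1:10) {
    g2 <- as_similarity_graph(random_weight_graph(sample(3:10, 1)))
    expect_identical(newman_girvan_modularity(g2, rep(1, nrow(g2$weights))), 0)
  }
})

test_that("modularity agrees with the brute-force double-sum oracle", {
  set.seed(7)
  for (k in 1:30) {
    n <- sample(3:12, 1)
    w <- random_weight_graph(n)
    if (sum(w) == 0) next
    membership <- sample(1:2, n, replace = TRUE)
    expect_equal(
      newman_girvan_modularity(as_similarity_graph(w), membership),
      brute_modularity(w, membership), tolerance = 1e-10)
  }
})

test_that("empty graph yields Q = 0 with a warning", {
  g <- as_similarity_graph(matrix(0, 3, 3))
  expect_warning(q <- newman_girvan_modularity(g, c(1, 2, 2)), "empty")
  expect_identical(q, 0)
})

test_that("spectral bipartition separates obvious structure", {
  # orthogonal rows: one per side
  m <- toy_counts(rbind(c(5, 0), c(0, 5)))
  sp <- spectral_bipartition(m)
  expect_false(is.null(sp))
  expect_setequal(c(sp$A, sp$B), c("c1", "c2"))
  expect_length(sp$A, 1)

  # identical rows: degenerate, do not split
  expect_null(spectral_bipartition(toy_counts(rbind(c(2, 1), c(2, 1), c(2, 1)))))
  expect_error(spectral_bipartition(m, "c1"), "at least 2")
})

test_that("spectral bipartition recovers two planted blocks", {
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_block_counts(block_spec(n_cells_per_block = c(50, 50),
      seed = s))
    m <- tfidf_normalize(filter_matrix(sim$matrix))
    sp <- spectral_bipartition(m)
    part <- stats::setNames(rep(2L, length(m$barcodes)), m$barcodes)
    part[sp$A] <- 1L
    if (rand_index(part[m$barcodes], sim$true_labels[m$barcodes]) >= 0.95) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("build_tree output conserves barcodes and numbers nodes breadth-first", {
  sim <- simulate_block_counts(block_spec(n_cells_per_block = c(30, 30),
    seed = 2))
  m <- tfidf_normalize(filter_matrix(sim$matrix))
  t <- build_tree(m)
  expect_silent(validate_tree(t))
  expect_setequal(tree_cells(t), m$barcodes)
  ids <- vapply(tree_nodes(t), `[[`, integer(1), "node_id")
  expect_equal(ids, seq_along(ids) - 1L)  # bfs ids 0..n-1 in bfs order
  # internal distances are the split modularities: positive, leaves zero
  for (node in tree_nodes(t)) {
    if (is_leaf(node)) expect_identical(node$distance, 0)
    else expect_gt(node$distance, 0)
  }
})

test_that("raising min_modularity never increases node count", {
  sim <- simulate_block_counts(block_spec(seed = 3))
  m <- tfidf_normalize(filter_matrix(sim$matrix))
  counts <- vapply(c(0, 0.01, 0.05, 0.2),
    function(q) length(tree_nodes(build_tree(m, min_modularity = q))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  # a prohibitive threshold gives the single-leaf tree
  expect_equal(length(tree_nodes(build_tree(m, min_modularity = 1))), 1L)
})

test_that("build_tree is invariant to cell input order up to renumbering", {
  sim <- simulate_block_counts(block_spec(n_cells_per_block = c(25, 25),
    seed = 8))
  m <- tfidf_normalize(filter_matrix(sim$matrix))
  set.seed(1)
  perm <- sample(length(m$barcodes))
  m2 <- count_matrix(m$counts[perm, ], barcodes = m$barcodes[perm],
    feature_names = m$feature_names, normalized = "tfidf")
  t1 <- build_tree(m)
  t2 <- build_tree(m2)
  p1 <- leaf_partition(t1)
  p2 <- leaf_partition(t2)
  cells <- tree_cells(t1)
  expect_equal(rand_index(p1[cells], p2[cells]), 1)
  d1 <- sort(distance_distribution(t1)$distance)
  d2 <- sort(distance_distribution(t2)$distance)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("build_tree stops on degenerate input", {
  m <- count_matrix(rbind(c(1, 2), c(1, 2), c(1, 2)),
    barcodes = c("a", "b", "c"), feature_names = c("g1", "g2"),
    normalized = "tfidf")
  t <- build_tree(m)
  expect_equal(n_leaves(t), 1L)
  expect_error(build_tree(count_matrix(matrix(numeric(), 0, 0),
    barcodes = character(), feature_names = character(),
    normalized = "tfidf")), "empty")
})
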