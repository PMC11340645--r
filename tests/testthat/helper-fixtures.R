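# Shared fixtures and independent oracles, built in code at test time.

# small raw count matrix with named axes
toy_counts <- function(x, barcodes = sprintf("c%d", seq_len(nrow(x))),
                       features = sprintf("g%d", seq_len(ncol(x)))) {
  count_matrix(x, barcodes = barcodes, feature_names = features,
    normalized = "raw")
}

# write a MatrixMarket bundle by hand (text), 10x orientation
# (features x cells); entries is a data.frame(row_feature, col_cell, value)
write_toy_bundle <- function(dir, n_features, n_cells, entries,
                             barcodes = sprintf("c%d", seq_len(n_cells)),
                             features = sprintf("g%d", seq_len(n_features)),
                             feature_cols = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    "%%MatrixMarket matrix coordinate integer general",
    sprintf("%d %d %d", n_features, n_cells, nrow(entries)),
    if (nrow(entries)) sprintf("%d %d %d", entries[[1]], entries[[2]], entries[[3]])
  ), file.path(dir, "matrix.mtx"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  ft <- if (feature_cols == 1L) features else {
    apply(cbind(paste0("ENSG", seq_along(features)), features,
      rep("Gene Expression", length(features)))[, seq_len(feature_cols),
        drop = FALSE], 1, paste, collapse = "\t")
  }
  writeLines(ft, file.path(dir, "features.tsv"))
  dir
}

# independent brute-force modularity oracle:
# Q = sum_ij (w_ij - k_i k_j / 2m) * delta(c_i, c_j) / 2m
brute_modularity <- function(w, membership) {
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      q <- q + (w[i, j] - k[i] * k[j] / two_m)
    }
  }
  q / two_m
}

# random symmetric non-negative weight matrix with zero diagonal
random_weight_graph <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  upper <- which(upper.tri(w))
  on <- upper[runif(length(upper)) < density]
  w[on] <- runif(length(on), 0.1, 2)
  w <- w + t(w)
  diag(w) <- 0
  w
}

as_similarity_graph <- function(w) {
  dimnames(w) <- list(sprintf("v%d", seq_len(nrow(w))),
    sprintf("v%d", seq_len(nrow(w))))
  structure(list(weights = w, total_weight = sum(w)),
    class = "similarity_graph")
}

# two disconnected unit-weight triangles (6 vertices)
two_triangles <- function() {
  w <- matrix(0, 6, 6)
  for (tri in list(1:3, 4:6)) {
    for (i in tri) for (j in tri) if (i != j) w[i, j] <- 1
  }
  as_similarity_graph(w)
}

# hand-built tree: root(0, d) -> leaves with given cell vectors
two_leaf_tree <- function(cells_a, cells_b, d = 0.5) {
  root <- list(node_id = 0L, distance = d, children = list(
    list(node_id = 1L, distance = 0, children = NULL, cells = cells_a),
    list(node_id = 2L, distance = 0, children = NULL, cells = cells_b)),
    cells = character())
  structure(list(root = root), class = "cluster_tree")
}

# balanced 4-leaf tree, ids breadth-first, distances per level
balanced_4leaf_tree <- function(d_root = 0.5, d_mid = c(0.3, 0.2),
                                cells_per_leaf = 2) {
  mk_leaf <- function(id, tag) list(node_id = id, distance = 0,
    children = NULL, cells = sprintf("%s-%d", tag, seq_len(cells_per_leaf)))
  root <- list(node_id = 0L, distance = d_root, cells = character(),
    children = list(
      list(node_id = 1L, distance = d_mid[1], cells = character(),
        children = list(mk_leaf(3L, "a"), mk_leaf(4L, "b"))),
      list(node_id = 2L, distance = d_mid[2], cells = character(),
        children = list(mk_leaf(5L, "c"), mk_leaf(6L, "d")))))
  structure(list(root = root), class = "cluster_tree")
}

# leaf-induced partition of barcodes, named by barcode
leaf_partition <- function(t) {
  leaves <- Filter(is_leaf, tree_nodes(t))
  unlist(lapply(seq_along(leaves), function(i) {
    stats::setNames(rep(i, length(leaves[[i]]$cells)), leaves[[i]]$cells)
  }))
}

# plain (unadjusted) Rand index between two labelings of the same items
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / choose(n, 2)
}

# count matrix + matching random vector for overlay property tests
random_tree_and_vector <- function(n_leaves, seed) {
  t <- simulate_random_tree(n_leaves, cells_per_leaf = sample(2:6, 1),
    seed = seed)
  cells <- tree_cells(t)
  v <- stats::setNames(rnorm(length(cells)), cells)
  list(tree = t, v = v)
}
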