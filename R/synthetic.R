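# Synthetic data: planted block-structured counts and random trees --------

#' Specification of a planted block-structured count matrix
#'
#' Describes a cell population made of transcriptionally distinct blocks:
#' counts are negative binomial with mean \code{baseline_mean} everywhere
#' except on each block's private marker features, whose within-block mean
#' is \code{baseline_mean * marker_fold}. Marker sets are disjoint across
#' blocks. The dispersion parameter is the standard scRNA-seq
#' overdispersion (NB variance \code{mu + dispersion * mu^2}), shared
#' across features.
#'
#' The defaults emulate a small droplet-style experiment: 150 cells over
#' 2000 genes at baseline mean 0.3 (roughly 800 transcripts per cell with
#' about three-quarters of entries zero, so cells pass the standard
#' 250-transcript filter), 5\% of genes as 8-fold markers per block, and
#' NB dispersion 0.5.
#'
#' @param n_cells_per_block positive integer vector, one entry per block
#' @param n_features total number of features
#' @param n_marker_features_per_block markers private to each block
#' @param marker_fold mean multiplier on a block's markers (> 1 plants
#'   structure; exactly 1 is the homogeneous null)
#' @param baseline_mean NB mean off-marker
#' @param dispersion NB overdispersion (NB \code{size = 1/dispersion})
#' @param seed integer seed making generation deterministic
#' @return a \code{block_spec} list
#' @export
block_spec <- function(n_cells_per_block = c(50, 50, 50), n_features = 2000,
                       n_marker_features_per_block = 100, marker_fold = 8,
                       baseline_mean = 0.3, dispersion = 0.5, seed = 1L) {
  spec <- list(
    n_cells_per_block = as.integer(n_cells_per_block),
    n_features = as.integer(n_features),
    n_marker_features_per_block = as.integer(n_marker_features_per_block),
    marker_fold = as.numeric(marker_fold),
    baseline_mean = as.numeric(baseline_mean),
    dispersion = as.numeric(dispersion),
    seed = as.integer(seed)
  )
  if (any(spec$n_cells_per_block < 1)) {
    stop("block_spec: every block needs at least one cell", call. = FALSE)
  }
  n_blocks <- length(spec$n_cells_per_block)
  if (n_blocks * spec$n_marker_features_per_block > spec$n_features) {
    stop(sprintf(
      "block_spec: %d blocks x %d markers exceed %d features",
      n_blocks, spec$n_marker_features_per_block, spec$n_features), call. = FALSE)
  }
  if (spec$marker_fold < 1) stop("block_spec: marker_fold must be >= 1", call. = FALSE)
  if (spec$baseline_mean <= 0 || spec$dispersion <= 0) {
    stop("block_spec: baseline_mean and dispersion must be positive", call. = FALSE)
  }
  structure(spec, class = "block_spec")
}

#' Simulate a count matrix with planted hierarchical block structure
#'
#' Draws negative binomial counts per \code{\link{block_spec}}. Block
#' \code{b}'s markers are features
#' \code{(b-1)*k + 1, ..., b*k} (\code{k} markers per block), so marker
#' sets are disjoint and recovery criteria unambiguous.
#'
#' @param spec a \code{\link{block_spec}}
#' @return list with \code{matrix} (a raw \code{\link{count_matrix}}) and
#'   \code{true_labels} (named character vector, barcode -> block label)
#' @export
simulate_block_counts <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  set.seed(spec$seed)
  n_blocks <- length(spec$n_cells_per_block)
  n_cells <- sum(spec$n_cells_per_block)
  k <- spec$n_marker_features_per_block
  block_of <- rep(seq_len(n_blocks), spec$n_cells_per_block)
  mu <- matrix(spec$baseline_mean, nrow = n_cells, ncol = spec$n_features)
  for (b in seq_len(n_blocks)) {
    if (k > 0) {
      markers <- ((b - 1L) * k + 1L):(b * k)
      mu[block_of == b, markers] <- spec$baseline_mean * spec$marker_fold
    }
  }
  counts <- matrix(
    stats::rnbinom(n_cells * spec$n_features, mu = as.vector(mu),
      size = 1 / spec$dispersion),
    nrow = n_cells, ncol = spec$n_features)
  barcodes <- sprintf("cell-%04d", seq_len(n_cells))
  features <- sprintf("gene-%03d", seq_len(spec$n_features))
  labels <- stats::setNames(sprintf("block%d", block_of), barcodes)
  list(
    matrix = count_matrix(counts, barcodes = barcodes, feature_names = features,
      normalized = "raw"),
    true_labels = labels
  )
}

#' Simulate a random full binary cluster tree
#'
#' Grows a full binary tree by repeatedly splitting a uniformly chosen
#' leaf until \code{n_leaves} leaves exist; internal nodes get independent
#' uniform split distances in (0, 1); each leaf owns
#' \code{cells_per_leaf} synthetic barcodes. Node ids are breadth-first
#' from 0.
#'
#' @param n_leaves number of leaves (>= 1)
#' @param cells_per_leaf cells owned by each leaf
#' @param seed integer seed
#' @return a \code{cluster_tree}
#' @export
simulate_random_tree <- function(n_leaves, cells_per_leaf = 5, seed = 1L) {
  if (n_leaves < 1) stop("simulate_random_tree: n_leaves must be >= 1", call. = FALSE)
  set.seed(seed)
  # represent the growing tree as nested lists of leaf slot indices
  shape <- 1L  # a single leaf, identified by its slot number
  n_slots <- 1L
  split_leaf <- function(node, target) {
    if (is.integer(node)) {
      if (node == target) {
        left <- n_slots + 1L
        right <- n_slots + 2L
        n_slots <<- n_slots + 2L
        return(list(d = stats::runif(1), l = left, r = right))
      }
      return(node)
    }
    node$l <- split_leaf(node$l, target)
    node$r <- split_leaf(node$r, target)
    node
  }
  collect_leaf_slots <- function(node) {
    if (is.integer(node)) return(node)
    c(collect_leaf_slots(node$l), collect_leaf_slots(node$r))
  }
  for (i in seq_len(n_leaves - 1L)) {
    leaves <- collect_leaf_slots(shape)
    target <- leaves[sample.int(length(leaves), 1L)]
    shape <- split_leaf(shape, target)
  }
  leaf_slots <- collect_leaf_slots(shape)
  next_cell <- 0L
  to_node <- function(node) {
    if (is.integer(node)) {
      cells <- sprintf("sim-%05d", next_cell + seq_len(cells_per_leaf))
      next_cell <<- next_cell + as.integer(cells_per_leaf)
      return(new_node(distance = 0, cells = cells))
    }
    new_node(distance = node$d, children = list(to_node(node$l), to_node(node$r)))
  }
  renumber_bfs(new_tree(to_node(shape)))
}
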