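# Per-node statistics: feature means, label composition, two-feature
# high/low classification, tooltip records ------------------------------

#' Per-node mean of a cell-aligned feature vector
#'
#' For every node of the tree, the mean of \code{v} over the node's cells
#' (leaves: own cells; internal nodes: union of descendants). The
#' aggregation satisfies the conservation identity: a parent's mean equals
#' the cell-count-weighted mean of its children's means.
#'
#' @param t a \code{cluster_tree}
#' @param v numeric vector named by barcode, covering all tree barcodes
#' @param feature optional feature name recorded in the overlay metadata
#' @return a \code{node_overlay}: list with \code{values} (named numeric,
#'   node id -> mean), \code{kind = "mean_feature"} and \code{metadata}
#' @export
node_feature_means <- function(t, v, feature = NULL) {
  stopifnot(inherits(t, "cluster_tree"), is.numeric(v))
  missing <- setdiff(tree_cells(t), names(v))
  if (length(missing)) {
    stop(sprintf("node_feature_means: no value for barcode '%s'", missing[[1]]),
      call. = FALSE)
  }
  values <- numeric()
  walk <- function(node) {  # returns c(sum, n)
    if (is_leaf(node)) {
      acc <- c(sum(v[node$cells]), length(node$cells))
    } else {
      acc <- walk(node$children[[1]]) + walk(node$children[[2]])
    }
    values[[as.character(node$node_id)]] <<- acc[[1]] / acc[[2]]
    acc
  }
  walk(t$root)
  structure(list(values = values, kind = "mean_feature",
    metadata = list(feature = feature)), class = "node_overlay")
}

#' Per-node label composition
#'
#' Counts cells of each label under every node; an internal node's counts
#' are the sums of its children's.
#'
#' @param t a \code{cluster_tree}
#' @param labels a \code{label_map} covering every tree barcode
#' @return named list, node id (character) -> named integer vector of
#'   label counts
#' @export
node_label_composition <- function(t, labels) {
  stopifnot(inherits(t, "cluster_tree"), inherits(labels, "label_map"))
  missing <- setdiff(tree_cells(t), names(labels$label_of))
  if (length(missing)) {
    stop(sprintf("node_label_composition: barcode '%s' is unlabeled", missing[[1]]),
      call. = FALSE)
  }
  all_labels <- sort(unique(unname(labels$label_of)))
  comp <- list()
  walk <- function(node) {
    if (is_leaf(node)) {
      counts <- table(factor(labels$label_of[node$cells], levels = all_labels))
      counts <- stats::setNames(as.integer(counts), all_labels)
    } else {
      counts <- walk(node$children[[1]]) + walk(node$children[[2]])
    }
    comp[[as.character(node$node_id)]] <<- counts
    counts
  }
  walk(t$root)
  comp
}

#' Joint high/low classification of two features per node
#'
#' Each cell is classified against per-feature thresholds: A-high iff
#' \code{vA >= hiA}, A-low iff \code{vA <= loA} (same for B); cells in
#' neither band for either feature are indeterminate. Node values are the
#' proportions of the five joint categories among the node's cells.
#'
#' @param t a \code{cluster_tree}
#' @param vA,vB numeric vectors named by barcode
#' @param hiA,loA,hiB,loB thresholds with \code{lo <= hi} per feature
#' @return a \code{node_overlay} with \code{kind = "two_feature"};
#'   \code{values} is a matrix (rows = node ids, columns = the five
#'   category proportions, each row summing to 1)
#' @export
two_feature_classification <- function(t, vA, vB, hiA, loA, hiB, loB) {
  stopifnot(inherits(t, "cluster_tree"))
  if (loA > hiA || loB > hiB) {
    stop("two_feature_classification: lo threshold exceeds hi", call. = FALSE)
  }
  cells <- tree_cells(t)
  missing <- setdiff(cells, intersect(names(vA), names(vB)))
  if (length(missing)) {
    stop(sprintf("two_feature_classification: no value for barcode '%s'",
      missing[[1]]), call. = FALSE)
  }
  class_of <- function(v, hi, lo) {
    ifelse(v >= hi, "high", ifelse(v <= lo, "low", "mid"))
  }
  ca <- class_of(vA[cells], hiA, loA)
  cb <- class_of(vB[cells], hiB, loB)
  categories <- c("A-high/B-high", "A-high/B-low", "A-low/B-high",
    "A-low/B-low", "indeterminate")
  joint <- ifelse(ca == "mid" | cb == "mid", "indeterminate",
    paste0("A-", ca, "/B-", cb))
  joint <- stats::setNames(factor(joint, levels = categories), cells)
  ids <- vapply(tree_nodes(t), `[[`, integer(1), "node_id")
  values <- base::t(vapply(tree_nodes(t), function(node) {
    own <- node_cells(node)
    as.vector(table(joint[own])) / length(own)
  }, numeric(length(categories))))
  dimnames(values) <- list(as.character(ids), categories)
  structure(list(values = values, kind = "two_feature",
    metadata = list(hiA = hiA, loA = loA, hiB = hiB, loB = loB)),
    class = "node_overlay")
}

#' Tooltip-style statistics for one node
#'
#' The content of an interactive node tooltip as plain data: cell count,
#' split distance, depth, optional label composition and overlay value.
#'
#' @param t a \code{cluster_tree}
#' @param node_id node to describe
#' @param labels optional \code{label_map}
#' @param overlay optional \code{node_overlay}
#' @return list with \code{node_id}, \code{n_cells}, \code{distance},
#'   \code{depth}, \code{is_leaf}, and, when available,
#'   \code{label_composition} and \code{overlay_value}
#' @export
node_statistics <- function(t, node_id, labels = NULL, overlay = NULL) {
  node <- tree_find_node(t, node_id)
  key <- as.character(node_id)
  out <- list(
    node_id = node$node_id,
    n_cells = length(node_cells(node)),
    distance = node$distance,
    depth = unname(node_depths(t)[[key]]),
    is_leaf = is_leaf(node))
  if (!is.null(labels)) {
    out$label_composition <- node_label_composition(t, labels)[[key]]
  }
  if (!is.null(overlay)) {
    out$overlay_value <- if (is.matrix(overlay$values)) {
      overlay$values[key, ]
    } else {
      unname(overlay$values[[key]])
    }
  }
  out
}
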