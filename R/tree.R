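# Cluster tree container ------------------------------------------------
#
# A node is a plain list:
#   node_id  integer
#   distance numeric >= 0 (modularity of the split below this node; 0 at leaves)
#   children NULL (leaf) or list of exactly two nodes
#   cells    character barcodes (non-empty only at leaves)
# A cluster_tree wraps the root node; node ids are unique within a tree and
# assigned breadth-first from 0 at the root when built by build_tree().

new_node <- function(node_id = 0L, distance = 0, children = NULL,
                     cells = character()) {
  list(node_id = as.integer(node_id), distance = as.numeric(distance),
    children = children, cells = as.character(cells))
}

new_tree <- function(root) structure(list(root = root), class = "cluster_tree")

#' Is a tree node a leaf?
#' @param node a node of a \code{cluster_tree}
#' @return logical
#' @export
is_leaf <- function(node) is.null(node$children)

#' All nodes of a tree in breadth-first order
#' @param t a \code{cluster_tree}
#' @return list of node lists, root first
#' @export
tree_nodes <- function(t) {
  stopifnot(inherits(t, "cluster_tree"))
  out <- list()
  queue <- list(t$root)
  while (length(queue)) {
    node <- queue[[1]]
    queue <- queue[-1]
    out[[length(out) + 1L]] <- node
    if (!is_leaf(node)) queue <- c(queue, node$children)
  }
  out
}

#' Look up a node by id
#' @param t a \code{cluster_tree}
#' @param node_id integer node id
#' @return the node list
#' @export
tree_find_node <- function(t, node_id) {
  for (node in tree_nodes(t)) if (node$node_id == node_id) return(node)
  stop(sprintf("node id %s not found in tree", node_id), call. = FALSE)
}

#' Cells owned by a node (its leaf descendants' barcodes)
#' @param node a node of a \code{cluster_tree}
#' @return character vector of barcodes
#' @export
node_cells <- function(node) {
  if (is_leaf(node)) return(node$cells)
  c(node_cells(node$children[[1]]), node_cells(node$children[[2]]))
}

#' All barcodes of a tree (the root's cells)
#' @param t a \code{cluster_tree}
#' @return character vector of barcodes
#' @export
tree_cells <- function(t) node_cells(t$root)

#' Number of leaves of a tree
#' @param t a \code{cluster_tree}
#' @return integer
#' @export
n_leaves <- function(t) sum(vapply(tree_nodes(t), is_leaf, logical(1)))

#' Depth of each node (root = 0)
#' @param t a \code{cluster_tree}
#' @return named integer vector, names are node ids in breadth-first order
#' @export
node_depths <- function(t) {
  depths <- integer()
  walk <- function(node, d) {
    depths[[as.character(node$node_id)]] <<- d
    if (!is_leaf(node)) for (ch in node$children) walk(ch, d + 1L)
  }
  walk(t$root, 0L)
  ids <- vapply(tree_nodes(t), `[[`, integer(1), "node_id")
  depths[as.character(ids)]
}

# Reassign node ids breadth-first from 0 at the root. Ids are attached by
# structural path (1 = first child, 2 = second) collected in level order.
renumber_bfs <- function(t) {
  queue <- list(list(node = t$root, path = integer(0)))
  order_paths <- list()
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    order_paths[[length(order_paths) + 1L]] <- cur$path
    if (!is_leaf(cur$node)) {
      queue <- c(queue,
        list(list(node = cur$node$children[[1]], path = c(cur$path, 1L))),
        list(list(node = cur$node$children[[2]], path = c(cur$path, 2L))))
    }
  }
  set_id <- function(nd, path, id) {
    if (!length(path)) {
      nd$node_id <- id
      return(nd)
    }
    nd$children[[path[[1]]]] <- set_id(nd$children[[path[[1]]]], path[-1], id)
    nd
  }
  root <- t$root
  for (k in seq_along(order_paths)) {
    root <- set_id(root, order_paths[[k]], k - 1L)
  }
  new_tree(root)
}

#' Validate the structural invariants of a cluster tree
#'
#' Checks that every node has zero or two children, that node ids are
#' unique, that barcodes appear in exactly one leaf, and that internal
#' nodes own no cells directly.
#'
#' @param t a \code{cluster_tree}
#' @return invisibly \code{TRUE}; stops with a message naming the offending
#'   node id otherwise
#' @export
validate_tree <- function(t) {
  stopifnot(inherits(t, "cluster_tree"))
  ids <- integer()
  barcodes <- character()
  walk <- function(node) {
    if (!is.null(node$children) && length(node$children) != 2L) {
      stop(sprintf("tree validation: node %d has %d children (must be 0 or 2)",
        node$node_id, length(node$children)), call. = FALSE)
    }
    if (!is.na(match(node$node_id, ids))) {
      stop(sprintf("tree validation: duplicate node id %d", node$node_id),
        call. = FALSE)
    }
    ids <<- c(ids, node$node_id)
    if (is_leaf(node)) {
      if (!length(node$cells)) {
        stop(sprintf("tree validation: leaf node %d owns no cells", node$node_id),
          call. = FALSE)
      }
      barcodes <<- c(barcodes, node$cells)
    } else {
      if (length(node$cells)) {
        stop(sprintf("tree validation: internal node %d owns cells directly",
          node$node_id), call. = FALSE)
      }
      for (ch in node$children) walk(ch)
    }
    if (!is.finite(node$distance) || node$distance < 0) {
      stop(sprintf("tree validation: node %d has invalid distance",
        node$node_id), call. = FALSE)
    }
  }
  walk(t$root)
  dup <- barcodes[duplicated(barcodes)]
  if (length(dup)) {
    stop(sprintf("tree validation: barcode '%s' appears in more than one leaf",
      dup[[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cluster_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  cat(sprintf("<cluster_tree> %d nodes, %d leaves, %d cells\n",
    length(nodes), n_leaves(x), length(tree_cells(x))))
  invisible(x)
}
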