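# Structural tree editing with a replayable history ----------------------

collapse_to_leaf <- function(node) {
  new_node(node_id = node$node_id, distance = 0, cells = node_cells(node))
}

#' Prune a tree by minimum node size
#'
#' Bottom-up: whenever either child of a node holds fewer than \code{n}
#' cells, both children are removed and the parent becomes a leaf owning
#' their cells (a binary tree cannot drop a single child). After pruning,
#' every node except possibly the root holds at least \code{n} cells; the
#' root's cell multiset is unchanged.
#'
#' @param t a \code{cluster_tree}
#' @param n minimum number of cells per surviving node (>= 1)
#' @return the pruned \code{cluster_tree}
#' @export
prune_min_cells <- function(t, n) {
  stopifnot(inherits(t, "cluster_tree"), n >= 1)
  walk <- function(node) {
    if (is_leaf(node)) return(node)
    node$children <- lapply(node$children, walk)
    sizes <- vapply(node$children, function(ch) length(node_cells(ch)), integer(1))
    if (any(sizes < n)) return(collapse_to_leaf(node))
    node
  }
  new_tree(walk(t$root))
}

#' Prune a tree by minimum split distance
#'
#' Top-down from the root: any internal node whose distance is strictly
#' below \code{cutoff} has its entire subtree collapsed into it (the node
#' becomes a leaf owning all descendant cells); descendants of collapsed
#' nodes are not visited. A cutoff of 0 is the identity since distances
#' are non-negative and the comparison is strict.
#'
#' @param t a \code{cluster_tree}
#' @param cutoff non-negative distance cutoff (the drug-persister case
#'   study uses 0.019 to surface small subpopulations)
#' @return the pruned \code{cluster_tree}
#' @export
prune_min_distance <- function(t, cutoff) {
  stopifnot(inherits(t, "cluster_tree"), cutoff >= 0)
  walk <- function(node) {
    if (is_leaf(node)) return(node)
    if (node$distance < cutoff) return(collapse_to_leaf(node))
    node$children <- lapply(node$children, walk)
    node
  }
  new_tree(walk(t$root))
}

#' Prune a tree to a maximum depth
#'
#' Nodes at depth \code{d} (root = 0) become leaves owning their
#' descendants' cells.
#'
#' @param t a \code{cluster_tree}
#' @param d depth at which to cut (>= 0)
#' @return the pruned \code{cluster_tree}
#' @export
prune_depth <- function(t, d) {
  stopifnot(inherits(t, "cluster_tree"), d >= 0)
  walk <- function(node, depth) {
    if (is_leaf(node)) return(node)
    if (depth >= d) return(collapse_to_leaf(node))
    node$children <- lapply(node$children, walk, depth = depth + 1L)
    node
  }
  new_tree(walk(t$root, 0L))
}

#' Re-root a tree at a node
#'
#' Returns the subtree rooted at \code{node_id} as a standalone tree.
#' Original node ids and distances are preserved so overlays computed on
#' the full tree remain cross-referenceable; cells outside the subtree are
#' dropped.
#'
#' @param t a \code{cluster_tree}
#' @param node_id id of the new root
#' @return a \code{cluster_tree}
#' @export
set_root <- function(t, node_id) {
  stopifnot(inherits(t, "cluster_tree"))
  new_tree(tree_find_node(t, node_id))
}

#' A single structural edit step
#'
#' @param kind one of \code{"min_cells"}, \code{"min_distance_search"},
#'   \code{"depth"}, \code{"set_root"}
#' @param value threshold (first three kinds) or node id (\code{set_root})
#' @return a \code{prune_step}
#' @export
prune_step <- function(kind = c("min_cells", "min_distance_search", "depth",
                                "set_root"), value) {
  kind <- match.arg(kind)
  value <- as.numeric(value)
  if (!is.finite(value)) stop("prune_step: value must be finite", call. = FALSE)
  if (kind %in% c("min_cells", "depth", "set_root") && value != round(value)) {
    stop(sprintf("prune_step: %s needs an integer value", kind), call. = FALSE)
  }
  min_ok <- switch(kind, min_cells = 1, 0)
  if (value < min_ok) {
    stop(sprintf("prune_step: %s needs a value >= %g", kind, min_ok),
      call. = FALSE)
  }
  structure(list(kind = kind, value = value), class = "prune_step")
}

#' An ordered, replayable prune history
#'
#' The breadcrumb trail of structural edits: replaying a history on the
#' original tree is deterministic, and replaying a prefix implements undo.
#'
#' @param ... \code{prune_step} objects (or a single list of them)
#' @return a \code{prune_history}
#' @export
prune_history <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && !inherits(steps[[1]], "prune_step") &&
      is.list(steps[[1]])) {
    steps <- steps[[1]]
  }
  for (s in steps) {
    if (!inherits(s, "prune_step")) {
      stop("prune_history: all elements must be prune_step objects", call. = FALSE)
    }
  }
  structure(list(steps = steps), class = "prune_history")
}

apply_step <- function(t, step) {
  switch(step$kind,
    min_cells = prune_min_cells(t, step$value),
    min_distance_search = prune_min_distance(t, step$value),
    depth = prune_depth(t, step$value),
    set_root = set_root(t, as.integer(step$value)),
    stop(sprintf("unknown prune step kind '%s'", step$kind), call. = FALSE))
}

#' Replay a prune history on a tree
#'
#' Left-fold of the steps over the tree; an error in step \code{k} is
#' reported with its index.
#'
#' @param t a \code{cluster_tree}
#' @param h a \code{prune_history}
#' @return the edited \code{cluster_tree}
#' @export
apply_history <- function(t, h) {
  stopifnot(inherits(t, "cluster_tree"), inherits(h, "prune_history"))
  for (k in seq_along(h$steps)) {
    t <- tryCatch(apply_step(t, h$steps[[k]]), error = function(e) {
      stop(sprintf("apply_history: step %d (%s) failed: %s", k,
        h$steps[[k]]$kind, conditionMessage(e)), call. = FALSE)
    })
  }
  t
}

#' Distribution of internal-node split distances
#'
#' Lists every internal node's distance in descending order, the basis for
#' choosing distance-pruning cutoffs.
#'
#' @param t a \code{cluster_tree}
#' @return data.frame with columns \code{node_id} and \code{distance},
#'   sorted by decreasing distance (empty for a leaf-only tree)
#' @export
distance_distribution <- function(t) {
  stopifnot(inherits(t, "cluster_tree"))
  nodes <- Filter(Negate(is_leaf), tree_nodes(t))
  df <- data.frame(
    node_id = vapply(nodes, `[[`, integer(1), "node_id"),
    distance = vapply(nodes, `[[`, numeric(1), "distance"))
  df[order(-df$distance), , drop = FALSE]
}
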