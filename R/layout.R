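# Radial tree layout ------------------------------------------------------

#' Radial layout of a cluster tree
#'
#' Places the root at the center (radius 0) with angular span
#' \code{[0, 2*pi)}; each child's span is the fraction of the parent's
#' span proportional to its leaf count (or cell count with
#' \code{weight = "cells"}); a node sits at its span midpoint. Radii grow
#' outward in uniform unit steps per level, or, with
#' \code{scale_by_distance = TRUE}, by the parent's split distance per
#' edge, floored at 1\% of the deepest cumulative distance so that
#' near-zero splits stay visible.
#'
#' @param t a \code{cluster_tree}
#' @param scale_by_distance use split distances as edge lengths?
#' @param weight \code{"leaves"} (default) or \code{"cells"}: how sibling
#'   angular spans are allocated
#' @return data.frame with one row per node: \code{node_id},
#'   \code{parent_id} (NA at root), \code{angle}, \code{radius},
#'   \code{span_start}, \code{span_end}, \code{is_leaf}, \code{n_cells}
#' @export
radial_layout <- function(t, scale_by_distance = FALSE,
                          weight = c("leaves", "cells")) {
  stopifnot(inherits(t, "cluster_tree"))
  weight <- match.arg(weight)
  node_weight <- function(node) {
    if (weight == "cells") return(length(node_cells(node)))
    if (is_leaf(node)) 1L else
      node_weight(node$children[[1]]) + node_weight(node$children[[2]])
  }
  eps_min <- 0.01
  if (scale_by_distance) {
    max_path <- function(node) {
      if (is_leaf(node)) return(0)
      node$distance + max(max_path(node$children[[1]]),
        max_path(node$children[[2]]))
    }
    deepest <- max_path(t$root)
    eps_min <- if (deepest > 0) 0.01 * deepest else 0.01
  }
  rows <- list()
  walk <- function(node, parent_id, start, end, radius) {
    rows[[length(rows) + 1L]] <<- data.frame(
      node_id = node$node_id, parent_id = parent_id,
      angle = (start + end) / 2, radius = radius,
      span_start = start, span_end = end,
      is_leaf = is_leaf(node), n_cells = length(node_cells(node)))
    if (is_leaf(node)) return(invisible())
    step <- if (scale_by_distance) max(node$distance, eps_min) else 1
    w1 <- node_weight(node$children[[1]])
    w2 <- node_weight(node$children[[2]])
    cut <- start + (end - start) * w1 / (w1 + w2)
    walk(node$children[[1]], node$node_id, start, cut, radius + step)
    walk(node$children[[2]], node$node_id, cut, end, radius + step)
  }
  walk(t$root, NA_integer_, 0, 2 * pi, 0)
  do.call(rbind, rows)
}

#' Per-node branch widths
#'
#' Maps node cell counts into a pixel width range:
#' \code{width = min + (max - min) * log1p(n_cells) / log1p(n_root)}.
#' The root always gets the maximum; every node has at least one cell so
#' widths stay strictly above the minimum.
#'
#' @param t a \code{cluster_tree}
#' @param range numeric length-2, \code{c(min, max)} pixel widths
#' @return named numeric vector, node id -> width
#' @export
compute_branch_widths <- function(t, range = c(1, 12)) {
  stopifnot(inherits(t, "cluster_tree"), length(range) == 2, range[1] <= range[2])
  nodes <- tree_nodes(t)
  n_root <- length(tree_cells(t))
  ids <- vapply(nodes, `[[`, integer(1), "node_id")
  sizes <- vapply(nodes, function(n) length(node_cells(n)), integer(1))
  stats::setNames(
    range[1] + (range[2] - range[1]) * log1p(sizes) / log1p(n_root),
    as.character(ids))
}
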