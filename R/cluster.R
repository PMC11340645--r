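# Tree construction: similarity graph, modularity, spectral bipartition ---

#' Truncated cosine similarity graph over a set of cells
#'
#' Builds the dense weighted graph on which split quality is evaluated:
#' \code{w(i,j) = max(0, cosine(row_i, row_j))} for \code{i != j}, zero
#' diagonal. Negative cosines are clipped to zero so all edge weights are
#' non-negative, as modularity requires.
#'
#' @param m a \code{\link{count_matrix}}
#' @param cell_subset character barcodes (default: all cells)
#' @return a \code{similarity_graph}: list with \code{weights} (symmetric
#'   matrix with barcode dimnames) and \code{total_weight} (the sum of all
#'   entries, i.e. twice the total edge weight)
#' @export
cosine_similarity_graph <- function(m, cell_subset = m$barcodes) {
  stopifnot(inherits(m, "count_matrix"), length(cell_subset) >= 1)
  idx <- match(cell_subset, m$barcodes)
  if (anyNA(idx)) {
    stop(sprintf("cosine_similarity_graph: unknown barcode '%s'",
      cell_subset[which(is.na(idx))[1]]), call. = FALSE)
  }
  x <- as.matrix(m$counts[idx, , drop = FALSE])
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    stop(sprintf("cosine_similarity_graph: cell '%s' has zero norm",
      cell_subset[which(norms == 0)[1]]), call. = FALSE)
  }
  xn <- x / norms
  w <- xn %*% t(xn)
  w[w < 0] <- 0
  diag(w) <- 0
  w <- (w + t(w)) / 2  # enforce exact symmetry against rounding
  dimnames(w) <- list(cell_subset, cell_subset)
  structure(list(weights = w, total_weight = sum(w)), class = "similarity_graph")
}

#' Newman-Girvan modularity of a two-way partition
#'
#' \code{Q = sum_i (e_ii - a_i^2)} where \code{e_ii} is the fraction of
#' total edge weight falling inside community \code{i} and \code{a_i} the
#' fraction of edge ends attached to community \code{i}. \code{Q} lies in
#' \code{[-0.5, 1]}; the single-community partition has \code{Q = 0}
#' exactly, and \code{Q > 0} means more within-community weight than
#' expected under the degree-preserving random null.
#'
#' @param g a \code{similarity_graph} from
#'   \code{\link{cosine_similarity_graph}} (any symmetric non-negative
#'   weight matrix wrapped in the same structure works)
#' @param partition vector of community memberships, one entry per graph
#'   vertex in graph order (any two-level labelling; more than two
#'   communities are also accepted)
#' @return numeric Q
#' @export
newman_girvan_modularity <- function(g, partition) {
  stopifnot(inherits(g, "similarity_graph"))
  w <- g$weights
  n <- nrow(w)
  if (length(partition) != n) {
    stop("newman_girvan_modularity: partition must cover all graph vertices",
      call. = FALSE)
  }
  two_m <- g$total_weight
  if (two_m == 0) {
    warning("newman_girvan_modularity: empty graph (total weight 0); Q = 0")
    return(0)
  }
  part <- as.integer(factor(partition))
  if (length(unique(part)) == 1L) return(0)  # trivial partition: Q == 0 exactly
  degrees <- rowSums(w)
  q <- 0
  for (comm in unique(part)) {
    members <- part == comm
    e_ii <- sum(w[members, members, drop = FALSE]) / two_m
    a_i <- sum(degrees[members]) / two_m
    q <- q + e_ii - a_i^2
  }
  q
}

#' Spectral bipartition of a set of cells
#'
#' Splits cells by the sign of the second left singular vector of the
#' row-L2-normalized submatrix (LSA-style). The sign convention fixes the
#' largest-magnitude component of the vector positive; zero components go
#' to side A. When the second singular value is (numerically) zero — e.g.
#' all rows identical — the split is degenerate and \code{NULL} is
#' returned, signalling "do not split".
#'
#' @param m a \code{\link{count_matrix}} (normally TF-IDF normalized)
#' @param cell_subset character barcodes, at least 2
#' @param tol relative tolerance on the second singular value below which
#'   the split is declared degenerate
#' @return \code{NULL} (degenerate) or a list with character vectors
#'   \code{A} and \code{B}, both non-empty
#' @export
spectral_bipartition <- function(m, cell_subset = m$barcodes, tol = 1e-8) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(cell_subset) < 2) {
    stop("spectral_bipartition: need at least 2 cells", call. = FALSE)
  }
  idx <- match(cell_subset, m$barcodes)
  if (anyNA(idx)) {
    stop(sprintf("spectral_bipartition: unknown barcode '%s'",
      cell_subset[which(is.na(idx))[1]]), call. = FALSE)
  }
  x <- as.matrix(m$counts[idx, , drop = FALSE])
  norms <- sqrt(rowSums(x^2))
  norms[norms == 0] <- 1  # zero rows stay zero and land on side A
  xn <- x / norms
  sv <- svd(xn, nu = 2, nv = 0)
  if (length(sv$d) < 2 || sv$d[2] <= tol * sv$d[1]) return(NULL)
  u2 <- sv$u[, 2]
  if (u2[which.max(abs(u2))] < 0) u2 <- -u2
  # ties: numerically zero components default to side A, unless the
  # negative side would be empty, in which case they form side B (e.g.
  # two exactly orthogonal cells, whose split vector is {0, +})
  tol_zero <- tol * max(abs(u2))
  pos <- u2 > tol_zero
  neg <- u2 < -tol_zero
  zero <- !pos & !neg
  side_a <- pos | zero
  side_b <- neg
  if (!any(side_b)) {
    if (any(zero) && any(pos)) {
      side_a <- pos
      side_b <- zero
    } else {
      return(NULL)
    }
  }
  list(A = cell_subset[side_a], B = cell_subset[side_b])
}

#' Build a cluster tree by recursive spectral bipartition
#'
#' At each node the cells are split by \code{\link{spectral_bipartition}};
#' the split is accepted iff its Newman-Girvan modularity on the truncated
#' cosine similarity graph of the node's cells exceeds
#' \code{min_modularity}, both sides are non-empty, and the node holds at
#' least \code{min_split_size} cells. An accepted node stores the split's
#' modularity as its \code{distance}; rejected nodes become leaves with
#' distance 0. Node ids are assigned breadth-first from 0 at the root.
#'
#' @param m a normalized, filtered \code{\link{count_matrix}} (TF-IDF
#'   recommended; raw input is accepted but a warning is issued)
#' @param min_modularity splits with Q at or below this are rejected
#'   (default 0: keep splitting while better than random)
#' @param min_split_size do not attempt to split nodes smaller than this
#' @param max_depth optional maximum depth; nodes at this depth are leaves
#' @return a \code{cluster_tree}
#' @export
build_tree <- function(m, min_modularity = 0, min_split_size = 2,
                       max_depth = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(m$barcodes) == 0) stop("build_tree: empty matrix", call. = FALSE)
  if (m$normalized == "raw") {
    warning("build_tree: input is raw; TF-IDF normalization is recommended")
  }
  grow <- function(cells, depth) {
    if (length(cells) < max(2L, min_split_size) ||
        (!is.null(max_depth) && depth >= max_depth)) {
      return(new_node(distance = 0, cells = cells))
    }
    split <- spectral_bipartition(m, cells)
    if (is.null(split)) return(new_node(distance = 0, cells = cells))
    g <- cosine_similarity_graph(m, cells)
    membership <- ifelse(cells %in% split$A, 0L, 1L)
    q <- newman_girvan_modularity(g, membership)
    if (!(q > min_modularity)) return(new_node(distance = 0, cells = cells))
    new_node(distance = q,
      children = list(grow(split$A, depth + 1L), grow(split$B, depth + 1L)))
  }
  renumber_bfs(new_tree(grow(m$barcodes, 0L)))
}
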