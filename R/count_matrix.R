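#' Construct a cell-by-feature count matrix
#'
#' The central container of the package: a sparse non-negative matrix with
#' cells on rows and features (genes) on columns, plus a normalization tag.
#' Raw matrices must hold integer counts; normalized matrices hold reals.
#'
#' @param counts matrix or Matrix, cells x features, non-negative
#' @param barcodes character vector of unique cell identifiers (defaults to
#'   rownames)
#' @param feature_names character vector of unique feature identifiers
#'   (defaults to colnames)
#' @param normalized one of \code{"raw"}, \code{"tfidf"},
#'   \code{"upper_quartile"}
#' @return an object of class \code{count_matrix} with elements
#'   \code{counts} (a \code{dgCMatrix}), \code{barcodes},
#'   \code{feature_names} and \code{normalized}
#' @export
count_matrix <- function(counts, barcodes = rownames(counts),
                         feature_names = colnames(counts),
                         normalized = c("raw", "tfidf", "upper_quartile")) {
  normalized <- match.arg(normalized)
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(barcodes) || is.null(feature_names)) {
    stop("count_matrix: barcodes and feature_names are required", call. = FALSE)
  }
  barcodes <- as.character(barcodes)
  feature_names <- as.character(feature_names)
  if (nrow(counts) != length(barcodes) || ncol(counts) != length(feature_names)) {
    stop(sprintf(
      "count_matrix: counts is %d x %d but %d barcodes / %d feature names given",
      nrow(counts), ncol(counts), length(barcodes), length(feature_names)
    ), call. = FALSE)
  }
  if (anyDuplicated(barcodes)) stop("count_matrix: duplicate barcodes", call. = FALSE)
  if (anyDuplicated(feature_names)) stop("count_matrix: duplicate feature names", call. = FALSE)
  x <- counts@x
  if (any(!is.finite(x))) stop("count_matrix: non-finite entries", call. = FALSE)
  if (any(x < 0)) stop("count_matrix: negative entries", call. = FALSE)
  if (normalized == "raw" && length(x) && any(x != round(x))) {
    stop("count_matrix: raw matrix must contain integer counts", call. = FALSE)
  }
  dimnames(counts) <- list(barcodes, feature_names)
  structure(
    list(counts = counts, barcodes = barcodes, feature_names = feature_names,
         normalized = normalized),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  nnz <- length(x$counts@x)
  cat(sprintf(
    "<count_matrix> %d cells x %d features (%s), %d nonzero entries (%.2f%% dense)\n",
    length(x$barcodes), length(x$feature_names), x$normalized, nnz,
    100 * nnz / max(1, prod(dim(x$counts)))
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# subset by row/col index or name, preserving class and order
subset_count_matrix <- function(m, cells = NULL, features = NULL) {
  i <- if (is.null(cells)) seq_along(m$barcodes) else cells
  j <- if (is.null(features)) seq_along(m$feature_names) else features
  count_matrix(m$counts[i, j, drop = FALSE],
    barcodes = m$barcodes[if (is.character(i)) match(i, m$barcodes) else i],
    feature_names = m$feature_names[if (is.character(j)) match(j, m$feature_names) else j],
    normalized = m$normalized
  )
}
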