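#' Read a 10x-style MatrixMarket bundle
#'
#' Reads \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv}
#' (optionally \code{.gz}-compressed; \code{genes.tsv} is accepted as a
#' synonym for \code{features.tsv}) from a directory. By the 10x convention
#' the MTX file stores features on rows and cells on columns; it is
#' transposed to cells x features on read. \code{features.tsv} may have two
#' or three tab-separated columns, in which case the second column (the
#' human-readable name) is used.
#'
#' @param dir_path directory containing the bundle
#' @param orientation \code{"features_x_cells"} (10x default) or
#'   \code{"cells_x_features"}
#' @return a raw \code{\link{count_matrix}}
#' @export
read_mtx_bundle <- function(dir_path,
                            orientation = c("features_x_cells", "cells_x_features")) {
  orientation <- match.arg(orientation)
  if (!dir.exists(dir_path)) {
    stop(sprintf("read_mtx_bundle: directory not found: %s", dir_path), call. = FALSE)
  }
  find1 <- function(stems) {
    for (stem in stems) for (ext in c("", ".gz")) {
      p <- file.path(dir_path, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stop(sprintf("read_mtx_bundle: missing file %s in %s", stems[[1]], dir_path),
      call. = FALSE)
  }
  mtx_path <- find1("matrix.mtx")
  bc_path <- find1("barcodes.tsv")
  ft_path <- find1(c("features.tsv", "genes.tsv"))

  .counter_bump("matrix_read")

  read_col <- function(path, which_col = 1L) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- if (length(parts)) length(parts[[1]]) else 1L
    k <- min(which_col, ncols)
    vapply(parts, `[[`, character(1), k)
  }
  barcodes <- read_col(bc_path)
  features <- read_col(ft_path, which_col = 2L)

  con <- if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path) else mtx_path
  mm <- tryCatch(Matrix::readMM(con),
    error = function(e) stop(sprintf("read_mtx_bundle: cannot parse %s: %s",
      mtx_path, conditionMessage(e)), call. = FALSE))
  mm <- methods::as(methods::as(methods::as(mm, "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (orientation == "features_x_cells") mm <- Matrix::t(mm)
  if (nrow(mm) != length(barcodes) || ncol(mm) != length(features)) {
    stop(sprintf(paste0(
      "read_mtx_bundle: dimension mismatch: matrix is %d cells x %d features ",
      "but found %d barcodes and %d feature names"),
      nrow(mm), ncol(mm), length(barcodes), length(features)), call. = FALSE)
  }
  if (length(mm@x) && (any(!is.finite(mm@x)) || any(mm@x < 0))) {
    stop("read_mtx_bundle: matrix contains negative or non-finite entries",
      call. = FALSE)
  }
  count_matrix(mm, barcodes = barcodes, feature_names = features, normalized = "raw")
}

#' Write a count matrix as a MatrixMarket bundle
#'
#' Inverse of \code{\link{read_mtx_bundle}}: writes \code{matrix.mtx}
#' (features x cells, 10x orientation), \code{barcodes.tsv} and
#' \code{features.tsv} into \code{dir_path}.
#'
#' @param m a \code{\link{count_matrix}}
#' @param dir_path output directory (created if absent)
#' @return invisibly, the directory path
#' @export
write_mtx_bundle <- function(m, dir_path) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir_path, "matrix.mtx"))
  writeLines(m$barcodes, file.path(dir_path, "barcodes.tsv"))
  writeLines(m$feature_names, file.path(dir_path, "features.tsv"))
  invisible(dir_path)
}

#' Filter cells by transcript count, then features by detection
#'
#' Cells whose total transcript count falls below \code{min_transcripts}
#' (inclusive threshold: a cell with exactly \code{min_transcripts} is kept)
#' are removed first; features detected (count > 0) in fewer than
#' \code{min_cells_per_feature} of the surviving cells are then removed.
#' Axis orderings are preserved; the pass is not iterated to a fixpoint.
#'
#' @param m a raw \code{\link{count_matrix}}
#' @param min_transcripts minimum per-cell total count (default 250)
#' @param min_cells_per_feature minimum number of surviving cells detecting
#'   a feature (default 1)
#' @return the filtered raw \code{\link{count_matrix}}
#' @export
filter_matrix <- function(m, min_transcripts = 250, min_cells_per_feature = 1) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalized != "raw") {
    stop("filter_matrix: matrix is already normalized; filter raw counts",
      call. = FALSE)
  }
  keep_cells <- which(Matrix::rowSums(m$counts) >= min_transcripts)
  if (!length(keep_cells)) {
    stop(sprintf("filter_matrix: no cell reaches %d transcripts", min_transcripts),
      call. = FALSE)
  }
  sub <- m$counts[keep_cells, , drop = FALSE]
  keep_feats <- which(Matrix::colSums(sub > 0) >= min_cells_per_feature)
  count_matrix(sub[, keep_feats, drop = FALSE],
    barcodes = m$barcodes[keep_cells],
    feature_names = m$feature_names[keep_feats],
    normalized = "raw")
}

#' TF-IDF normalization
#'
#' Term frequency-inverse document frequency weighting of a raw count
#' matrix: \code{value(c,g) = count(c,g) / rowsum(c) * ln(N / df_g)} where
#' \code{N} is the number of cells and \code{df_g} the number of cells in
#' which feature \code{g} is detected. Zeros stay zero; features detected in
#' every cell get weight \code{ln(1) = 0} and their column becomes zero.
#'
#' @param m a raw, filtered \code{\link{count_matrix}} (no zero-total cells)
#' @return a \code{count_matrix} with \code{normalized = "tfidf"}
#' @export
tfidf_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalized != "raw") stop("tfidf_normalize: matrix must be raw", call. = FALSE)
  totals <- Matrix::rowSums(m$counts)
  if (any(totals == 0)) {
    stop("tfidf_normalize: zero-total cell present; run filter_matrix first",
      call. = FALSE)
  }
  n_cells <- nrow(m$counts)
  df <- Matrix::colSums(m$counts > 0)
  idf <- ifelse(df > 0, log(n_cells / pmax(df, 1)), 0)
  out <- Matrix::Diagonal(x = 1 / totals) %*% m$counts %*% Matrix::Diagonal(x = idf)
  out <- methods::as(methods::as(methods::as(out, "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  out <- Matrix::drop0(out)
  count_matrix(out, barcodes = m$barcodes, feature_names = m$feature_names,
    normalized = "tfidf")
}

#' Upper-quartile normalization
#'
#' Divides each cell's counts by the 75th percentile of that cell's nonzero
#' counts (linear interpolation between order statistics), then multiplies
#' by the median of the per-cell divisors so the overall scale is comparable
#' across cells.
#'
#' @param m a raw \code{\link{count_matrix}}
#' @return a \code{count_matrix} with \code{normalized = "upper_quartile"}
#' @export
upper_quartile_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalized != "raw") {
    stop("upper_quartile_normalize: matrix must be raw", call. = FALSE)
  }
  cm <- m$counts
  divisors <- vapply(seq_len(nrow(cm)), function(i) {
    x <- cm[i, ]
    x <- x[x > 0]
    if (!length(x)) {
      stop(sprintf("upper_quartile_normalize: cell '%s' has no nonzero counts",
        m$barcodes[i]), call. = FALSE)
    }
    unname(stats::quantile(x, 0.75, type = 7))
  }, numeric(1))
  scale_back <- stats::median(divisors)
  out <- Matrix::Diagonal(x = scale_back / divisors) %*% cm
  out <- methods::as(methods::as(methods::as(out, "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  count_matrix(out, barcodes = m$barcodes, feature_names = m$feature_names,
    normalized = "upper_quartile")
}
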