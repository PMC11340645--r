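# Group-versus-group differential expression -----------------------------

#' Differential expression between two cell groups
#'
#' For every feature: \code{log2fc = log2((mean_A + pseudocount) /
#' (mean_B + pseudocount))} on upper-quartile normalized counts (means
#' taken over all cells of the group, zeros included), with a
#' Mann-Whitney U p-value and Benjamini-Hochberg q-value across features.
#' The test uses exact enumeration for small groups (both sides <= 20,
#' no ties) and the tie-corrected normal approximation otherwise; the
#' two-sided test is the default, with a one-sided option
#' (\code{alternative = "greater"} tests A shifted above B).
#'
#' @param m_uq an upper-quartile normalized \code{\link{count_matrix}}
#'   (see \code{\link{upper_quartile_normalize}})
#' @param cells_A,cells_B disjoint, non-empty barcode sets
#' @param pseudocount added to both means before the ratio (default 1)
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}
#' @return data.frame with columns \code{feature}, \code{mean_A},
#'   \code{mean_B}, \code{log2fc}, \code{p}, \code{q}, one row per
#'   feature in matrix column order
#' @export
differential_log2fc <- function(m_uq, cells_A, cells_B, pseudocount = 1,
                                alternative = c("two.sided", "greater", "less")) {
  stopifnot(inherits(m_uq, "count_matrix"))
  alternative <- match.arg(alternative)
  if (m_uq$normalized != "upper_quartile") {
    warning("differential_log2fc: matrix is not upper-quartile normalized")
  }
  if (!length(cells_A) || !length(cells_B)) {
    stop("differential_log2fc: both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(cells_A, cells_B))) {
    stop("differential_log2fc: cell groups overlap", call. = FALSE)
  }
  ia <- match(cells_A, m_uq$barcodes)
  ib <- match(cells_B, m_uq$barcodes)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- c(cells_A[is.na(ia)], cells_B[is.na(ib)])[1]
    stop(sprintf("differential_log2fc: unknown barcode '%s'", bad), call. = FALSE)
  }
  xa <- as.matrix(m_uq$counts[ia, , drop = FALSE])
  xb <- as.matrix(m_uq$counts[ib, , drop = FALSE])
  mean_a <- colMeans(xa)
  mean_b <- colMeans(xb)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  exact <- length(ia) <= 20 && length(ib) <= 20
  p <- vapply(seq_len(ncol(xa)), function(j) {
    suppressWarnings(stats::wilcox.test(xa[, j], xb[, j],
      alternative = alternative, exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature = m_uq$feature_names, mean_A = unname(mean_a),
    mean_B = unname(mean_b), log2fc = unname(log2fc), p = p, q = q,
    stringsAsFactors = FALSE)
}

#' Write differential-expression results as TSV
#'
#' @param res result of \code{\link{differential_log2fc}}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_differential_tsv <- function(res, path) {
  utils::write.table(res[, c("feature", "log2fc", "p", "q")], path,
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
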