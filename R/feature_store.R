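# Persistent columnar feature store --------------------------------------
#
# Directory layout:
#   barcodes.txt   one barcode per line, store row order
#   index.tsv      two tab-separated columns: feature name, column file
#   columns/fNNNNNN.bin.gz
#                  gzip-compressed little-endian 8-byte IEEE reals, one
#                  value per barcode, store row order
# The store honors the single-import contract: after build_feature_store()
# runs once, any feature vector is retrievable without touching the source
# count matrix again (verified by the io_counters() instrumentation).

#' Import a count matrix into a persistent feature store
#'
#' Writes one compressed binary column per feature plus a name index, so
#' any number of overlays can be generated afterwards without re-reading
#' the source matrix.
#'
#' @param m a \code{\link{count_matrix}}
#' @param path store directory
#' @param overwrite replace an existing non-empty directory?
#' @return an open \code{feature_store} handle
#' @export
build_feature_store <- function(m, path, overwrite = FALSE) {
  stopifnot(inherits(m, "count_matrix"))
  if (dir.exists(path) && length(list.files(path)) && !overwrite) {
    stop(sprintf(
      "build_feature_store: %s exists and is not empty (use overwrite = TRUE)",
      path), call. = FALSE)
  }
  unlink(path, recursive = TRUE)
  dir.create(file.path(path, "columns"), recursive = TRUE, showWarnings = FALSE)
  writeLines(m$barcodes, file.path(path, "barcodes.txt"))
  files <- sprintf("f%06d.bin.gz", seq_along(m$feature_names))
  dense <- as.matrix(m$counts)
  for (j in seq_along(m$feature_names)) {
    con <- gzfile(file.path(path, "columns", files[j]), "wb")
    writeBin(as.double(dense[, j]), con, size = 8L, endian = "little")
    close(con)
  }
  idx <- data.frame(feature = m$feature_names, file = files,
    stringsAsFactors = FALSE)
  utils::write.table(idx, file.path(path, "index.tsv"), sep = "\t",
    row.names = FALSE, col.names = TRUE, quote = FALSE)
  open_feature_store(path)
}

#' Open an existing feature store
#'
#' @param path store directory created by \code{\link{build_feature_store}}
#' @return a \code{feature_store} handle: list with \code{path},
#'   \code{barcodes} and the feature \code{index}
#' @export
open_feature_store <- function(path) {
  idx_path <- file.path(path, "index.tsv")
  bc_path <- file.path(path, "barcodes.txt")
  if (!file.exists(idx_path) || !file.exists(bc_path)) {
    stop(sprintf("open_feature_store: %s is not a feature store", path),
      call. = FALSE)
  }
  .counter_bump("store_open")
  idx <- utils::read.table(idx_path, sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, quote = "", comment.char = "")
  structure(
    list(path = path, barcodes = readLines(bc_path),
      index = stats::setNames(idx$file, idx$feature)),
    class = "feature_store")
}

#' Retrieve one feature's cell-aligned vector from a store
#'
#' Exact-name lookup; on a miss the error lists near-matches (substring
#' and approximate). Use \code{\link{search_features}} for interactive
#' discovery.
#'
#' @param s a \code{feature_store}
#' @param feature exact feature name
#' @return numeric vector named by barcode, in store row order
#' @export
get_feature_vector <- function(s, feature) {
  stopifnot(inherits(s, "feature_store"))
  file <- unname(s$index[feature])
  if (is.null(file) || is.na(file)) {
    near <- search_features(s, feature)
    if (!length(near)) near <- utils::head(agrep(feature, names(s$index),
      value = TRUE, ignore.case = TRUE, max.distance = 0.3), 5)
    hint <- if (length(near)) {
      sprintf("; near matches: %s", paste(utils::head(near, 5), collapse = ", "))
    } else ""
    stop(sprintf("get_feature_vector: feature '%s' not in store%s", feature, hint),
      call. = FALSE)
  }
  con <- gzfile(file.path(s$path, "columns", file), "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = length(s$barcodes), size = 8L,
    endian = "little")
  stats::setNames(v, s$barcodes)
}

#' Substring search over store feature names
#'
#' The scriptable counterpart of an interactive fuzzy-search bar:
#' case-insensitive fixed-substring match over the feature index.
#'
#' @param s a \code{feature_store}
#' @param pattern substring to look for
#' @return character vector of matching feature names
#' @export
search_features <- function(s, pattern) {
  stopifnot(inherits(s, "feature_store"))
  names(s$index)[grepl(pattern, names(s$index), fixed = TRUE, ignore.case = FALSE) |
      grepl(tolower(pattern), tolower(names(s$index)), fixed = TRUE)]
}
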