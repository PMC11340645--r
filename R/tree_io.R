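# Tree and label serialization -------------------------------------------
#
# cluster_tree.json dialect: a recursive node object
#   {"_id": int, "_distance": real,
#    "_cells": [{"barcode": str}, ...]   (leaves only)
#    "children": [node, node]}           (internal nodes only)
# Key order is stable (_id, _distance, then _cells or children); distances
# are written at full double precision so that read . write is the
# identity; files are UTF-8 and readers are gzip-transparent.

node_to_json_list <- function(node) {
  out <- list(`_id` = node$node_id, `_distance` = node$distance)
  if (is_leaf(node)) {
    out$`_cells` <- lapply(node$cells, function(b) list(barcode = b))
  } else {
    out$children <- list(node_to_json_list(node$children[[1]]),
      node_to_json_list(node$children[[2]]))
  }
  out
}

#' Write a cluster tree to JSON
#'
#' @param t a \code{cluster_tree}
#' @param path output file (\code{.gz} suffix writes gzip)
#' @return invisibly, \code{path}
#' @seealso \code{\link{read_tree_json}}
#' @export
write_tree_json <- function(t, path) {
  stopifnot(inherits(t, "cluster_tree"))
  json <- jsonlite::toJSON(node_to_json_list(t$root), auto_unbox = TRUE,
    digits = NA)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  ok <- tryCatch({
    writeLines(json, con, useBytes = TRUE)
    TRUE
  }, error = function(e) {
    stop(sprintf("write_tree_json: cannot write %s: %s", path,
      conditionMessage(e)), call. = FALSE)
  }, finally = close(con))
  invisible(path)
}

json_list_to_node <- function(obj) {
  for (key in c("_id", "_distance")) {
    if (is.null(obj[[key]])) {
      stop(sprintf("read_tree_json: node missing required key '%s'", key),
        call. = FALSE)
    }
  }
  id <- obj[["_id"]]
  children <- NULL
  cells <- character()
  if (!is.null(obj[["children"]])) {
    if (length(obj[["children"]]) != 2L) {
      stop(sprintf(
        "read_tree_json: node %s has %d children (must be exactly 2)",
        id, length(obj[["children"]])), call. = FALSE)
    }
    if (!is.null(obj[["_cells"]]) && length(obj[["_cells"]])) {
      stop(sprintf("read_tree_json: internal node %s also lists cells", id),
        call. = FALSE)
    }
    children <- lapply(obj[["children"]], json_list_to_node)
  } else {
    cells <- vapply(obj[["_cells"]], function(c) {
      if (is.null(c$barcode)) {
        stop(sprintf("read_tree_json: cell entry in node %s lacks 'barcode'", id),
          call. = FALSE)
      }
      as.character(c$barcode)
    }, character(1))
  }
  new_node(node_id = id, distance = obj[["_distance"]], children = children,
    cells = cells)
}

#' Read a cluster tree from JSON
#'
#' Parses and validates a file written by \code{\link{write_tree_json}}.
#' Trees with one-child nodes, duplicate node ids or duplicate barcodes
#' are rejected with an error naming the offending node.
#'
#' @param path JSON file (gzip-transparent)
#' @return a validated \code{cluster_tree}
#' @export
read_tree_json <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_tree_json: file not found: %s", path), call. = FALSE)
  }
  .counter_bump("tree_parse")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  close(con)
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) stop(sprintf("read_tree_json: malformed JSON in %s: %s",
      path, conditionMessage(e)), call. = FALSE))
  t <- new_tree(json_list_to_node(obj))
  validate_tree(t)
  t
}

# fixed categorical palette for auto-assigned label colors (12-class)
.label_palette <- c(
  "#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD", "#8C564B",
  "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF", "#AEC7E8", "#FFBB78"
)

#' Read a cell label CSV
#'
#' Expects a header with columns \code{item,label} and optionally
#' \code{color} (hex \code{#RRGGBB}, honored verbatim). Without a color
#' column, colors are assigned from a fixed categorical palette in
#' label-sorted order (recycled beyond 12 labels).
#'
#' @param path CSV file (gzip-transparent)
#' @return a \code{label_map}: list with \code{label_of} (named character,
#'   barcode -> label) and \code{color_of} (named character, label -> hex)
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_labels_csv: file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("item", "label") %in% names(df))) {
    stop("read_labels_csv: header must contain columns 'item' and 'label'",
      call. = FALSE)
  }
  if (anyDuplicated(df$item)) {
    dup <- df$item[duplicated(df$item)][1]
    stop(sprintf("read_labels_csv: item '%s' appears more than once", dup),
      call. = FALSE)
  }
  if (any(!nzchar(df$label))) {
    stop("read_labels_csv: empty label strings are not allowed", call. = FALSE)
  }
  label_map(stats::setNames(as.character(df$label), df$item),
    colors = if ("color" %in% names(df)) {
      cf <- unique(df[, c("label", "color")])
      if (anyDuplicated(cf$label)) {
        stop("read_labels_csv: conflicting colors for one label", call. = FALSE)
      }
      stats::setNames(cf$color, cf$label)
    } else NULL)
}

#' Construct a label map
#'
#' @param label_of named character vector, barcode -> label
#' @param colors optional named character vector, label -> hex color;
#'   missing labels get palette colors in label-sorted order
#' @return a \code{label_map}
#' @export
label_map <- function(label_of, colors = NULL) {
  stopifnot(is.character(label_of), !is.null(names(label_of)))
  labels <- sort(unique(unname(label_of)))
  auto <- stats::setNames(
    rep_len(.label_palette, length(labels)), labels)
  if (!is.null(colors)) {
    bad <- colors[!grepl("^#[0-9A-Fa-f]{6}$", colors)]
    if (length(bad)) {
      stop(sprintf("label_map: invalid hex color '%s' (need #RRGGBB)", bad[[1]]),
        call. = FALSE)
    }
    auto[names(colors)] <- colors
  }
  structure(list(label_of = label_of, color_of = auto), class = "label_map")
}

#' Write a label CSV
#'
#' @param labels a \code{label_map}
#' @param path output CSV
#' @return invisibly, \code{path}
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  df <- data.frame(item = names(labels$label_of),
    label = unname(labels$label_of),
    color = unname(labels$color_of[labels$label_of]),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
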