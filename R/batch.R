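# Headless config-driven batch rendering ---------------------------------

#' Describe a batch rendering job
#'
#' One figure per feature, all driven by a single base configuration,
#' a tree file and a feature store. The source count matrix is never
#' touched: the store is the only data source.
#'
#' @param base_config a \code{\link{render_config}}
#' @param features character vector of feature names (one figure each)
#' @param tree_path path to a cluster tree JSON file
#' @param store_path path to a \code{\link{build_feature_store}} directory
#' @param out_dir output directory (created if absent)
#' @param format \code{"svg"} or \code{"png"} (defaults to the config's
#'   export field)
#' @return a \code{batch_job}
#' @export
batch_job <- function(base_config = render_config(), features, tree_path,
                      store_path, out_dir, format = base_config$export) {
  stopifnot(inherits(base_config, "render_config"))
  format <- match.arg(format, c("svg", "png"))
  structure(list(base_config = base_config, features = as.character(features),
    tree_path = tree_path, store_path = store_path, out_dir = out_dir,
    format = format), class = "batch_job")
}

#' Run a batch rendering job
#'
#' Parses the tree exactly once and opens the feature store exactly once,
#' then streams through the feature list: retrieve the vector, aggregate
#' per-node means, render, write \code{<feature>.<ext>}. A missing
#' feature is recorded as a per-feature failure and the batch continues;
#' failures are attached to the result and raised as a warning.
#'
#' @param job a \code{\link{batch_job}}
#' @return character vector of written file paths, with a
#'   \code{"failures"} attribute (named character vector of error
#'   messages, empty on full success)
#' @export
run_batch <- function(job) {
  stopifnot(inherits(job, "batch_job"))
  t <- read_tree_json(job$tree_path)
  t <- apply_history(t, job$base_config$prune_history)
  store <- open_feature_store(job$store_path)
  dir.create(job$out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- radial_layout(t,
    scale_by_distance = job$base_config$scale_by_distance)
  written <- character()
  failures <- character()
  for (feature in job$features) {
    res <- tryCatch({
      v <- get_feature_vector(store, feature)
      ov <- node_feature_means(t, v, feature = feature)
      out <- file.path(job$out_dir,
        sprintf("%s.%s", gsub("[/\\\\]", "_", feature), job$format))
      if (job$format == "svg") {
        write_svg(render_svg(t, config = job$base_config, layout = layout,
          overlay = ov), out)
      } else {
        render_png(t, out, config = job$base_config, layout = layout,
          overlay = ov)
      }
      out
    }, error = function(e) structure(conditionMessage(e), class = "batch_fail"))
    if (inherits(res, "batch_fail")) {
      failures[[feature]] <- unclass(res)
    } else {
      written <- c(written, res)
    }
  }
  if (length(failures)) {
    warning(sprintf("run_batch: %d of %d features failed (%s)",
      length(failures), length(job$features),
      paste(names(failures), collapse = ", ")))
  }
  attr(written, "failures") <- failures
  written
}
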