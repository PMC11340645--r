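# Render configuration: a complete serializable description of one figure

.config_version <- "tmctree-config/1"

#' Construct a render configuration
#'
#' A \code{render_config} captures everything needed to reproduce one
#' figure headlessly: branch scaling, widths, label colors, up to two
#' feature overlays with high/low thresholds, the prune history to replay,
#' export format and canvas size.
#'
#' @param scale_by_distance scale branch lengths by split distance?
#' @param global_scale multiplier on the drawn tree radius (> 0)
#' @param branch_width_range numeric \code{c(min, max)} pixel widths
#' @param color_map named character vector, label -> hex \code{#RRGGBB}
#' @param feature_overlays list of up to two
#'   \code{list(feature =, hi =, lo =)} entries
#' @param prune_history a \code{\link{prune_history}} replayed before
#'   rendering
#' @param export \code{"svg"} or \code{"png"}
#' @param width_px,height_px canvas size in pixels
#' @param show_legend draw a legend?
#' @param seed integer recorded for provenance of any randomized styling
#' @return a \code{render_config}
#' @export
render_config <- function(scale_by_distance = FALSE, global_scale = 1,
                          branch_width_range = c(1, 12),
                          color_map = character(),
                          feature_overlays = list(),
                          prune_history = tmctree::prune_history(),
                          export = c("svg", "png"),
                          width_px = 800, height_px = 800,
                          show_legend = TRUE, seed = 1L) {
  export <- match.arg(export)
  cfg <- structure(list(
    scale_by_distance = isTRUE(scale_by_distance),
    global_scale = as.numeric(global_scale),
    branch_width_range = as.numeric(branch_width_range),
    color_map = color_map,
    feature_overlays = feature_overlays,
    prune_history = prune_history,
    export = export,
    width_px = as.numeric(width_px),
    height_px = as.numeric(height_px),
    show_legend = isTRUE(show_legend),
    seed = as.integer(seed)
  ), class = "render_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(path, msg) {
    stop(sprintf("render_config: %s: %s", path, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$global_scale) || cfg$global_scale <= 0) {
    fail("global_scale", "must be a positive number")
  }
  if (length(cfg$branch_width_range) != 2 ||
      cfg$branch_width_range[1] > cfg$branch_width_range[2]) {
    fail("branch_width_range", "must be c(min, max) with min <= max")
  }
  if (length(cfg$color_map)) {
    bad <- which(!grepl("^#[0-9A-Fa-f]{6}$", cfg$color_map))
    if (length(bad)) {
      fail(sprintf("color_map.%s", names(cfg$color_map)[bad[1]]),
        "colors must be hex #RRGGBB")
    }
  }
  if (length(cfg$feature_overlays) > 2) {
    fail("feature_overlays", "at most 2 overlays are supported")
  }
  for (k in seq_along(cfg$feature_overlays)) {
    ov <- cfg$feature_overlays[[k]]
    if (is.null(ov$feature)) {
      fail(sprintf("feature_overlays[%d].feature", k), "missing feature name")
    }
    hi <- if (is.null(ov$hi)) Inf else ov$hi
    lo <- if (is.null(ov$lo)) -Inf else ov$lo
    if (lo > hi) fail(sprintf("feature_overlays[%d]", k), "lo exceeds hi")
  }
  if (!inherits(cfg$prune_history, "prune_history")) {
    fail("prune_history", "must be a prune_history object")
  }
  if (!cfg$export %in% c("svg", "png")) fail("export", "must be 'svg' or 'png'")
  if (cfg$width_px <= 0 || cfg$height_px <= 0) {
    fail("width_px/height_px", "must be positive")
  }
  invisible(TRUE)
}

#' Serialize a render configuration to JSON
#'
#' @param cfg a \code{render_config}
#' @param path optional file; when \code{NULL} the JSON string is returned
#' @return the JSON string (invisibly when written to a file)
#' @export
config_to_json <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "render_config"))
  validate_config(cfg)
  obj <- list(
    version = .config_version,
    scale_by_distance = cfg$scale_by_distance,
    global_scale = cfg$global_scale,
    branch_width_range = cfg$branch_width_range,
    color_map = as.list(cfg$color_map),
    feature_overlays = lapply(cfg$feature_overlays, function(ov) {
      list(feature = ov$feature,
        hi = if (is.null(ov$hi)) NULL else ov$hi,
        lo = if (is.null(ov$lo)) NULL else ov$lo)
    }),
    prune_history = lapply(cfg$prune_history$steps, function(s) {
      list(kind = s$kind, value = s$value)
    }),
    export = cfg$export,
    width_px = cfg$width_px,
    height_px = cfg$height_px,
    show_legend = cfg$show_legend,
    seed = cfg$seed
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

#' Read a render configuration from JSON
#'
#' Strict: the \code{version} field must match, and unknown keys are
#' rejected with the offending path named.
#'
#' @param path JSON file, or a JSON string
#' @return a \code{render_config}
#' @export
config_from_json <- function(path) {
  txt <- if (file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    path
  }
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) stop(sprintf("config_from_json: malformed JSON: %s",
      conditionMessage(e)), call. = FALSE))
  known <- c("version", "scale_by_distance", "global_scale",
    "branch_width_range", "color_map", "feature_overlays", "prune_history",
    "export", "width_px", "height_px", "show_legend", "seed")
  unknown <- setdiff(names(obj), known)
  if (length(unknown)) {
    stop(sprintf("config_from_json: unknown key '%s'", unknown[[1]]),
      call. = FALSE)
  }
  if (is.null(obj$version) || !identical(obj$version, .config_version)) {
    stop(sprintf("config_from_json: version must be '%s' (got '%s')",
      .config_version, if (is.null(obj$version)) "<missing>" else obj$version),
      call. = FALSE)
  }
  steps <- lapply(seq_along(obj$prune_history), function(k) {
    s <- obj$prune_history[[k]]
    if (is.null(s$kind) || is.null(s$value)) {
      stop(sprintf("config_from_json: prune_history[%d] needs kind and value", k),
        call. = FALSE)
    }
    prune_step(s$kind, s$value)
  })
  overlays <- lapply(seq_along(obj$feature_overlays), function(k) {
    ov <- obj$feature_overlays[[k]]
    if (is.null(ov$feature)) {
      stop(sprintf("config_from_json: feature_overlays[%d].feature missing", k),
        call. = FALSE)
    }
    list(feature = ov$feature, hi = ov$hi, lo = ov$lo)
  })
  render_config(
    scale_by_distance = isTRUE(obj$scale_by_distance),
    global_scale = obj$global_scale,
    branch_width_range = as.numeric(unlist(obj$branch_width_range)),
    color_map = if (length(obj$color_map)) {
      stats::setNames(vapply(obj$color_map, as.character, character(1)),
        names(obj$color_map))
    } else character(),
    feature_overlays = overlays,
    prune_history = prune_history(steps),
    export = obj$export,
    width_px = obj$width_px,
    height_px = obj$height_px,
    show_legend = isTRUE(obj$show_legend),
    seed = obj$seed
  )
}
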