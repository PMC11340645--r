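# SVG / PNG figure generation --------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt <- function(x) formatC(x, format = "f", digits = 3, drop0trailing = TRUE)

polar_xy <- function(angle, radius, cx, cy, px_per_unit) {
  # SVG y grows downward; angle 0 points right, increasing counterclockwise
  c(cx + px_per_unit * radius * cos(angle),
    cy - px_per_unit * radius * sin(angle))
}

# linear two-color interpolation in RGB space over [0, 1]
interp_hex <- function(frac, low_hex, high_hex) {
  lo <- grDevices::col2rgb(low_hex)[, 1]
  hi <- grDevices::col2rgb(high_hex)[, 1]
  mix <- round(lo + frac * (hi - lo))
  grDevices::rgb(mix[1], mix[2], mix[3], maxColorValue = 255)
}

# map node overlay values onto [0,1]; constant overlays map to 1
overlay_fracs <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(stats::setNames(rep(1, length(values)), names(values)))
  (values - rng[1]) / diff(rng)
}

#' Render a cluster tree as an SVG document
#'
#' Draws the radial tree: one path per parent-to-child link (an arc along
#' the parent's radius followed by a radial segment) and one glyph group
#' per node, carrying its node id in a \code{data-node-id} attribute for
#' downstream tooling. Node glyphs are pies of label composition when
#' \code{labels} is given, circles colored by a continuous two-color
#' scale when a \code{node_overlay} of means is given, and plain circles
#' otherwise. The overlay color scale is monotone: a higher node mean
#' never maps to a lower position between \code{overlay_low_color} and
#' \code{overlay_high_color}.
#'
#' @param t a \code{cluster_tree} (already pruned; the config's
#'   \code{prune_history} is NOT replayed here — see \code{\link{run_batch}})
#' @param config a \code{\link{render_config}}
#' @param layout optional precomputed \code{\link{radial_layout}}
#' @param overlay optional \code{node_overlay} of per-node means
#' @param labels optional \code{label_map} for pie glyphs and legend
#' @param overlay_low_color,overlay_high_color hex endpoints of the
#'   feature color scale
#' @return the SVG document as a single character string
#' @export
render_svg <- function(t, config = render_config(), layout = NULL,
                       overlay = NULL, labels = NULL,
                       overlay_low_color = "#E5E5E5",
                       overlay_high_color = "#B2182B") {
  stopifnot(inherits(t, "cluster_tree"), inherits(config, "render_config"))
  if (is.null(layout)) {
    layout <- radial_layout(t, scale_by_distance = config$scale_by_distance)
  }
  ids <- as.character(layout$node_id)
  tree_ids <- vapply(tree_nodes(t), `[[`, integer(1), "node_id")
  if (!all(as.character(tree_ids) %in% ids)) {
    stop("render_svg: layout does not cover every tree node", call. = FALSE)
  }
  if (!is.null(overlay)) {
    vals <- if (is.matrix(overlay$values)) overlay$values[, 1] else overlay$values
    if (!all(as.character(tree_ids) %in% names(vals))) {
      stop("render_svg: overlay missing values for some tree nodes", call. = FALSE)
    }
    fracs <- overlay_fracs(vals)
  }
  comp <- if (!is.null(labels)) node_label_composition(t, labels)
  w <- config$width_px
  h <- config$height_px
  cx <- w / 2
  cy <- h / 2
  max_r <- max(layout$radius, 1e-9)
  px_per_unit <- 0.42 * min(w, h) * config$global_scale / max_r
  widths <- compute_branch_widths(t, config$branch_width_range)
  rows_by_id <- split(layout, ids)[ids]
  names(rows_by_id) <- ids

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" ",
      "height=\"%s\" viewBox=\"0 0 %s %s\">"), fmt(w), fmt(h), fmt(w), fmt(h)),
    sprintf("<rect width=\"%s\" height=\"%s\" fill=\"#FFFFFF\"/>", fmt(w), fmt(h))
  )

  # links: arc at parent radius from parent angle to child angle, then
  # radial segment out to the child
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    if (is.na(row$parent_id)) next
    parent <- layout[layout$node_id == row$parent_id, ]
    p0 <- polar_xy(parent$angle, parent$radius, cx, cy, px_per_unit)
    p1 <- polar_xy(row$angle, parent$radius, cx, cy, px_per_unit)
    p2 <- polar_xy(row$angle, row$radius, cx, cy, px_per_unit)
    arc_r <- px_per_unit * parent$radius
    sweep <- if (row$angle > parent$angle) 0 else 1  # svg y-flip inverts sweep
    d <- if (arc_r > 1e-9) {
      sprintf("M %s %s A %s %s 0 0 %d %s %s L %s %s",
        fmt(p0[1]), fmt(p0[2]), fmt(arc_r), fmt(arc_r), sweep,
        fmt(p1[1]), fmt(p1[2]), fmt(p2[1]), fmt(p2[2]))
    } else {
      sprintf("M %s %s L %s %s", fmt(p0[1]), fmt(p0[2]), fmt(p2[1]), fmt(p2[2]))
    }
    lines <- c(lines, sprintf(paste0("<path class=\"link\" data-child-id=\"%d\" ",
      "d=\"%s\" fill=\"none\" stroke=\"#555555\" stroke-width=\"%s\"/>"),
      row$node_id, d, fmt(widths[[as.character(row$node_id)]])))
  }

  # node glyphs
  glyph_r <- function(nid) {
    3 + 0.5 * widths[[as.character(nid)]]
  }
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    nid <- as.character(row$node_id)
    if (!row$node_id %in% tree_ids) next
    ctr <- polar_xy(row$angle, row$radius, cx, cy, px_per_unit)
    r <- glyph_r(row$node_id)
    inner <- if (!is.null(labels)) {
      pie_paths(comp[[nid]], ctr, r, labels$color_of, config$color_map)
    } else {
      fill <- if (!is.null(overlay)) {
        interp_hex(fracs[[nid]], overlay_low_color, overlay_high_color)
      } else "#4477AA"
      sprintf("<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"#333333\"/>",
        fmt(ctr[1]), fmt(ctr[2]), fmt(r), fill)
    }
    lines <- c(lines,
      sprintf("<g class=\"node\" data-node-id=\"%d\">", row$node_id),
      inner, "</g>")
  }

  if (config$show_legend) {
    lines <- c(lines, svg_legend(labels, overlay, config,
      overlay_low_color, overlay_high_color, w, h))
  }
  lines <- c(lines, "</svg>")
  paste(lines, collapse = "\n")
}

# pie wedges of a label composition; explicit config colors win over the
# label map's palette
pie_paths <- function(counts, ctr, r, palette, color_map) {
  counts <- counts[counts > 0]
  col_of <- function(lab) {
    if (length(color_map) && !is.null(color_map[[lab]]) &&
        !is.na(color_map[[lab]])) return(color_map[[lab]])
    palette[[lab]]
  }
  if (length(counts) == 1L) {
    return(sprintf(
      "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"#333333\"/>",
      fmt(ctr[1]), fmt(ctr[2]), fmt(r), col_of(names(counts))))
  }
  fracs <- counts / sum(counts)
  stops <- c(0, cumsum(fracs)) * 2 * pi
  out <- character()
  for (k in seq_along(counts)) {
    a0 <- stops[k]
    a1 <- stops[k + 1]
    p0 <- c(ctr[1] + r * cos(a0), ctr[2] - r * sin(a0))
    p1 <- c(ctr[1] + r * cos(a1), ctr[2] - r * sin(a1))
    large <- if ((a1 - a0) > pi) 1 else 0
    out <- c(out, sprintf(paste0(
      "<path d=\"M %s %s L %s %s A %s %s 0 %d 0 %s %s Z\" fill=\"%s\" ",
      "stroke=\"#333333\" stroke-width=\"0.5\"/>"),
      fmt(ctr[1]), fmt(ctr[2]), fmt(p0[1]), fmt(p0[2]), fmt(r), fmt(r),
      large, fmt(p1[1]), fmt(p1[2]), col_of(names(counts)[k])))
  }
  out
}

svg_legend <- function(labels, overlay, config, low_hex, high_hex, w, h) {
  out <- c(sprintf("<g class=\"legend\" transform=\"translate(%s %s)\">",
    fmt(12), fmt(16)))
  y <- 0
  if (!is.null(labels)) {
    for (lab in names(labels$color_of)) {
      col <- if (length(config$color_map) && !is.null(config$color_map[[lab]]) &&
          !is.na(config$color_map[[lab]])) config$color_map[[lab]]
        else labels$color_of[[lab]]
      out <- c(out,
        sprintf("<rect x=\"0\" y=\"%s\" width=\"12\" height=\"12\" fill=\"%s\"/>",
          fmt(y), col),
        sprintf("<text x=\"16\" y=\"%s\" font-size=\"11\">%s</text>",
          fmt(y + 10), xml_escape(lab)))
      y <- y + 16
    }
  }
  if (!is.null(overlay) && !is.matrix(overlay$values)) {
    rng <- range(overlay$values)
    out <- c(out,
      sprintf("<rect x=\"0\" y=\"%s\" width=\"12\" height=\"12\" fill=\"%s\"/>",
        fmt(y), low_hex),
      sprintf("<text x=\"16\" y=\"%s\" font-size=\"11\">low %s</text>",
        fmt(y + 10), fmt(rng[1])),
      sprintf("<rect x=\"0\" y=\"%s\" width=\"12\" height=\"12\" fill=\"%s\"/>",
        fmt(y + 16), high_hex),
      sprintf("<text x=\"16\" y=\"%s\" font-size=\"11\">high %s</text>",
        fmt(y + 26), fmt(rng[2])))
  }
  c(out, "</g>")
}

#' Write an SVG document to a file
#'
#' @param svg_doc string from \code{\link{render_svg}}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_svg <- function(svg_doc, path) {
  writeLines(svg_doc, path, useBytes = TRUE)
  invisible(path)
}

#' Render a cluster tree to a PNG file
#'
#' Draws the same radial layout as \code{\link{render_svg}} through R's
#' native \code{grDevices::png} bitmap device: links, node glyphs (solid
#' fill by overlay color or majority label color) and legend. The height
#' follows the configured aspect ratio, so the requested width is honored
#' and aspect preserved.
#'
#' @param t a \code{cluster_tree}
#' @param path output PNG file
#' @param config a \code{\link{render_config}}
#' @param layout optional precomputed \code{\link{radial_layout}}
#' @param overlay optional \code{node_overlay} of per-node means
#' @param labels optional \code{label_map}
#' @param width_px override the configured width
#' @param overlay_low_color,overlay_high_color feature color scale
#' @return invisibly, \code{path}
#' @export
render_png <- function(t, path, config = render_config(export = "png"),
                       layout = NULL, overlay = NULL, labels = NULL,
                       width_px = NULL,
                       overlay_low_color = "#E5E5E5",
                       overlay_high_color = "#B2182B") {
  stopifnot(inherits(t, "cluster_tree"), inherits(config, "render_config"))
  if (!capabilities("png")) {
    stop(paste0("render_png: this R build lacks PNG support; ",
      "export SVG instead (render_svg)"), call. = FALSE)
  }
  w <- if (is.null(width_px)) config$width_px else width_px
  h <- w * config$height_px / config$width_px
  if (is.null(layout)) {
    layout <- radial_layout(t, scale_by_distance = config$scale_by_distance)
  }
  tree_ids <- vapply(tree_nodes(t), `[[`, integer(1), "node_id")
  fracs <- NULL
  if (!is.null(overlay)) {
    vals <- if (is.matrix(overlay$values)) overlay$values[, 1] else overlay$values
    fracs <- overlay_fracs(vals)
  }
  comp <- if (!is.null(labels)) node_label_composition(t, labels)
  widths <- compute_branch_widths(t, config$branch_width_range)
  cx <- w / 2
  cy <- h / 2
  max_r <- max(layout$radius, 1e-9)
  px <- 0.42 * min(w, h) * config$global_scale / max_r

  grDevices::png(path, width = w, height = h)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0), asp = 1)
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    if (is.na(row$parent_id)) next
    parent <- layout[layout$node_id == row$parent_id, ]
    # arc approximated by short segments, then the radial edge
    angles <- seq(parent$angle, row$angle, length.out = 24)
    axy <- cbind(cx + px * parent$radius * cos(angles),
      cy - px * parent$radius * sin(angles))
    exy <- rbind(axy[nrow(axy), ],
      c(cx + px * row$radius * cos(row$angle),
        cy - px * row$radius * sin(row$angle)))
    lw <- widths[[as.character(row$node_id)]] / 2
    graphics::lines(axy[, 1], axy[, 2], col = "#555555", lwd = lw)
    graphics::lines(exy[, 1], exy[, 2], col = "#555555", lwd = lw)
  }
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    nid <- as.character(row$node_id)
    if (!row$node_id %in% tree_ids) next
    x <- cx + px * row$radius * cos(row$angle)
    y <- cy - px * row$radius * sin(row$angle)
    fill <- if (!is.null(fracs)) {
      interp_hex(fracs[[nid]], overlay_low_color, overlay_high_color)
    } else if (!is.null(comp)) {
      counts <- comp[[nid]]
      labels$color_of[[names(counts)[which.max(counts)]]]
    } else "#4477AA"
    graphics::points(x, y, pch = 21, bg = fill, col = "#333333",
      cex = 0.5 + 0.1 * widths[[nid]])
  }
  invisible(path)
}
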