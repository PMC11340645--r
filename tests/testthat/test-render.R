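test_that("radial layout divides the circle by leaf count", {
  t2 <- two_leaf_tree("a", "b")
  lay <- radial_layout(t2)
  root <- lay[lay$node_id == 0, ]
  l1 <- lay[lay$node_id == 1, ]
  l2 <- lay[lay$node_id == 2, ]
  expect_equal(root$radius, 0)
  expect_equal(c(l1$span_start, l1$span_end), c(0, pi))
  expect_equal(c(l2$span_start, l2$span_end), c(pi, 2 * pi))
  expect_equal(abs(l1$angle - l2$angle), pi)

  t4 <- balanced_4leaf_tree()
  lay4 <- radial_layout(t4, scale_by_distance = FALSE)
  leaves <- lay4[lay4$is_leaf, ]
  expect_equal(leaves$radius, rep(2, 4))  # uniform unit steps
  expect_equal(leaves$span_end - leaves$span_start, rep(pi / 2, 4))

  single <- radial_layout(simulate_random_tree(1, 3, seed = 1))
  expect_equal(nrow(single), 1L)
  expect_equal(single$radius, 0)
})

test_that("angular spans are conserved and siblings disjoint", {
  for (s in 1:10) {
    t <- simulate_random_tree(sample(2:20, 1), 2, seed = s)
    lay <- radial_layout(t, scale_by_distance = s %% 2 == 0)
    leaves <- lay[lay$is_leaf, ]
    expect_equal(sum(leaves$span_end - leaves$span_start), 2 * pi,
      tolerance = 1e-9)
    # leaf spans tile [0, 2pi) without overlap
    ord <- leaves[order(leaves$span_start), ]
    expect_true(all(abs(ord$span_start[-1] - ord$span_end[-nrow(ord)]) < 1e-9))
    # children's spans partition the parent's span
    for (i in which(!lay$is_leaf)) {
      kids <- lay[!is.na(lay$parent_id) & lay$parent_id == lay$node_id[i], ]
      expect_equal(sum(kids$span_end - kids$span_start),
        lay$span_end[i] - lay$span_start[i], tolerance = 1e-9)
    }
  }
})

test_that("distance scaling uses split distances with a visibility floor", {
  t <- balanced_4leaf_tree(d_root = 0.4, d_mid = c(0.2, 1e-9))
  lay <- radial_layout(t, scale_by_distance = TRUE)
  r_of <- function(id) lay$radius[lay$node_id == id]
  expect_equal(r_of(1), 0.4)
  expect_equal(r_of(3), 0.4 + 0.2)
  # near-zero split floored at 1% of the deepest cumulative distance
  expect_equal(r_of(5), 0.4 + 0.01 * 0.6)
})

test_that("branch widths interpolate on log cell counts", {
  t <- balanced_4leaf_tree(cells_per_leaf = 5)  # root 20, mid 10, leaf 5
  w <- compute_branch_widths(t, c(1, 12))
  expect_equal(unname(w[["0"]]), 12)
  expect_equal(unname(w[["1"]]), unname(w[["2"]]))  # equal siblings
  expect_equal(unname(w[["3"]]),
    1 + 11 * log1p(5) / log1p(20), tolerance = 1e-12)
  expect_true(all(w > 1))
})

test_that("SVG output has exact element counts and parses as XML", {
  t <- prune_depth(balanced_4leaf_tree(), 5)  # 4 leaves -> 7 nodes, 6 links
  svg <- render_svg(t)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  glyphs <- xml2::xml_find_all(doc, "//d1:g[@class='node']", ns)
  links <- xml2::xml_find_all(doc, "//d1:path[@class='link']", ns)
  expect_length(glyphs, 7)
  expect_length(links, 6)
  ids <- sort(as.integer(xml2::xml_attr(glyphs, "data-node-id")))
  expect_equal(ids, 0:6)
})

test_that("legend colors reproduce the configured hex values verbatim", {
  t <- two_leaf_tree(c("a1", "a2"), c("b1", "b2"))
  lm <- label_map(stats::setNames(c("x", "x", "y", "y"), tree_cells(t)))
  cfg <- render_config(color_map = c(x = "#ABCDEF", y = "#123456"))
  svg <- render_svg(t, config = cfg, labels = lm)
  expect_match(svg, "#ABCDEF", fixed = TRUE)
  expect_match(svg, "#123456", fixed = TRUE)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  legend_fills <- xml2::xml_attr(xml2::xml_find_all(doc,
    "//d1:g[@class='legend']/d1:rect", ns), "fill")
  expect_true(all(c("#ABCDEF", "#123456") %in% legend_fills))
})

test_that("the feature color scale is monotone in the node mean", {
  t <- balanced_4leaf_tree(cells_per_leaf = 3)
  cells <- tree_cells(t)
  v <- stats::setNames(seq_along(cells), cells)  # distinct leaf means
  ov <- node_feature_means(t, v)
  svg <- render_svg(t, overlay = ov, config = render_config(show_legend = FALSE))
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  glyphs <- xml2::xml_find_all(doc, "//d1:g[@class='node']", ns)
  ids <- xml2::xml_attr(glyphs, "data-node-id")
  fills <- xml2::xml_attr(xml2::xml_find_first(glyphs, "./d1:circle", ns),
    "fill")
  # green channel decreases from low (#E5E5E5) to high (#B2182B)
  green <- grDevices::col2rgb(fills)["green", ]
  means <- ov$values[ids]
  expect_equal(order(green), order(-means))
})

test_that("PNG export honors width and aspect ratio", {
  t <- balanced_4leaf_tree(cells_per_leaf = 3)
  f <- withr::local_tempfile(fileext = ".png")
  cfg <- render_config(export = "png", width_px = 400, height_px = 200)
  render_png(t, f, config = cfg)
  bytes <- readBin(f, "raw", 8)
  expect_identical(bytes, as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A,
    0x1A, 0x0A)))
  img <- png::readPNG(f)
  expect_equal(dim(img)[2], 400)
  expect_equal(dim(img)[1], 200)
  # explicit width override preserves aspect
  render_png(t, f, config = cfg, width_px = 200)
  expect_equal(dim(png::readPNG(f))[1:2], c(100, 200))
})

test_that("render configs round-trip through JSON and reject unknown keys", {
  cfg <- render_config(scale_by_distance = TRUE, global_scale = 1.5,
    branch_width_range = c(2, 9), color_map = c(tumor = "#FF0000"),
    feature_overlays = list(list(feature = "CD4", hi = 2, lo = 0.5)),
    prune_history = prune_history(prune_step("min_cells", 10),
      prune_step("min_distance_search", 0.019)),
    export = "png", width_px = 640, height_px = 480, show_legend = FALSE,
    seed = 7L)
  json <- config_to_json(cfg)
  cfg2 <- config_from_json(json)
  expect_equal(cfg2, cfg)
  # defaults round-trip too
  expect_equal(config_from_json(config_to_json(render_config())),
    render_config())
  expect_error(config_from_json('{"version":"tmctree-config/1","bogus":1}'),
    "bogus")
  expect_error(config_from_json('{"global_scale":2}'), "version")
  expect_error(render_config(feature_overlays = list(list(feature = "a"),
    list(feature = "b"), list(feature = "c"))), "at most 2")
  expect_error(render_config(color_map = c(x = "red")), "hex")
})

test_that("an embedded prune history replays to an identical tree", {
  t <- simulate_random_tree(10, 6, seed = 3)
  cfg <- render_config(prune_history = prune_history(
    prune_step("min_distance_search", 0.3), prune_step("min_cells", 12)))
  cfg2 <- config_from_json(config_to_json(cfg))
  direct <- prune_min_cells(prune_min_distance(t, 0.3), 12)
  expect_identical(apply_history(t, cfg2$prune_history), direct)
})
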