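Package: tmctree
Title: Hierarchical Spectral Clustering Trees for Single-Cell Count Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary cell-population trees from sparse single-cell
    count matrices by recursive spectral bipartition with a Newman-Girvan
    modularity stopping rule. Reads 10x-style MatrixMarket bundles, applies
    transcript filtering and TF-IDF or upper-quartile normalization, prunes
    and re-roots trees with a replayable edit history, overlays per-node
    label compositions and feature statistics backed by a single-import
    persistent feature store, computes group-versus-group differential
    expression (Mann-Whitney U with Benjamini-Hochberg correction), and
    batch-renders radial tree figures to SVG or PNG from a serializable
    configuration. Includes a synthetic-data generator with planted
    hierarchical block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    png,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
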