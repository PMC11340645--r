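test_that("read_mtx_bundle transcribes a 10x-style triplet bundle", {
  dir <- withr::local_tempdir()
  # features x cells: (g1,c1)=2, (g2,c3)=5
  write_toy_bundle(dir, n_features = 2, n_cells = 3,
    entries = data.frame(r = c(1, 2), c = c(1, 3), v = c(2, 5)))
  m <- read_mtx_bundle(dir)
  expect_s3_class(m, "count_matrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$normalized, "raw")
  dense <- as.matrix(m$counts)
  expect_equal(dense["c1", "g1"], 2)
  expect_equal(dense["c3", "g2"], 5)
  expect_equal(sum(dense), 7)  # four remaining entries are zero
})

test_that("read_mtx_bundle handles empty coordinates, 3-column features and gzip", {
  dir <- withr::local_tempdir()
  write_toy_bundle(dir, n_features = 2, n_cells = 2,
    entries = data.frame(r = integer(), c = integer(), v = integer()),
    feature_cols = 3L)
  m <- read_mtx_bundle(dir)
  expect_equal(as.vector(as.matrix(m$counts)), rep(0, 4))
  # 3-column features.tsv: column 2 is the name
  expect_equal(m$feature_names, c("g1", "g2"))

  # gzip-transparent: compress all three files
  for (f in c("matrix.mtx", "barcodes.tsv", "features.tsv")) {
    src <- file.path(dir, f)
    con <- gzfile(paste0(src, ".gz"), "wb")
    writeLines(readLines(src), con)
    close(con)
    unlink(src)
  }
  m2 <- read_mtx_bundle(dir)
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts))
})

test_that("read_mtx_bundle rejects inconsistent and missing inputs", {
  dir <- withr::local_tempdir()
  write_toy_bundle(dir, n_features = 2, n_cells = 4,
    entries = data.frame(r = 1, c = 1, v = 1),
    barcodes = sprintf("c%d", 1:3))  # 3 barcodes for 4 declared cells
  expect_error(read_mtx_bundle(dir), "dimension mismatch")

  dir2 <- withr::local_tempdir()
  write_toy_bundle(dir2, 2, 2, data.frame(r = 1, c = 1, v = 1))
  unlink(file.path(dir2, "barcodes.tsv"))
  expect_error(read_mtx_bundle(dir2), "barcodes.tsv")
})

test_that("mtx bundle round-trips through write_mtx_bundle", {
  m <- toy_counts(matrix(c(3, 0, 1, 0, 2, 7), nrow = 3))
  dir <- withr::local_tempdir()
  write_mtx_bundle(m, dir)
  m2 <- read_mtx_bundle(dir)
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts))
  expect_equal(m2$barcodes, m$barcodes)
  expect_equal(m2$feature_names, m$feature_names)
})

test_that("filter_matrix keeps cells at the inclusive transcript threshold", {
  m <- toy_counts(matrix(c(300, 249, 250), ncol = 1))
  f <- filter_matrix(m)
  expect_equal(f$barcodes, c("c1", "c3"))

  # cascade: a feature expressed only in a removed cell disappears
  x <- rbind(c(260, 0), c(100, 5))  # c2 dies; g2 was only in c2
  f2 <- filter_matrix(toy_counts(x))
  expect_equal(f2$barcodes, "c1")
  expect_equal(f2$feature_names, "g1")

  # zero thresholds are the identity
  f3 <- filter_matrix(toy_counts(x), min_transcripts = 0,
    min_cells_per_feature = 0)
  expect_equal(as.matrix(f3$counts), x, ignore_attr = TRUE)

  # idempotence
  f4 <- filter_matrix(f, min_transcripts = 250)
  expect_equal(as.matrix(f4$counts), as.matrix(f$counts))

  expect_error(filter_matrix(toy_counts(matrix(1:4, 2)), min_transcripts = 100),
    "no cell")
  expect_error(filter_matrix(tfidf_normalize(toy_counts(matrix(c(2, 0, 1, 1), 2,
    byrow = TRUE)))), "normalized")
})

test_that("tfidf_normalize matches the per-entry hand formula", {
  m <- toy_counts(matrix(c(2, 0, 1, 1), nrow = 2, byrow = TRUE))
  out <- tfidf_normalize(m)
  expect_equal(out$normalized, "tfidf")
  dense <- as.matrix(out$counts)
  # tf = [[1,0],[.5,.5]]; df = [2,1], N = 2 -> idf = [ln1, ln2]
  expect_equal(dense, matrix(c(0, 0, 0, 0.5 * log(2)), nrow = 2, byrow = TRUE),
    ignore_attr = TRUE, tolerance = 1e-12)

  # zeros stay zero; ubiquitous features zero out; other sparsity kept
  x <- rbind(c(5, 1, 0), c(3, 0, 2), c(2, 1, 1))
  tf <- as.matrix(tfidf_normalize(toy_counts(x))$counts)
  expect_true(all(tf[x == 0] == 0))
  expect_equal(unname(tf[, 1]), rep(0, 3))  # df = N
  expect_true(all((tf[, 2:3] > 0) == (x[, 2:3] > 0)))

  expect_error(tfidf_normalize(toy_counts(rbind(c(1, 1), c(0, 0)))),
    "zero-total")
})

test_that("upper_quartile_normalize scales by the nonzero 75th percentile", {
  # reference percentile oracle: linear interpolation (R type 7)
  expect_equal(unname(quantile(c(1, 2, 3, 4), 0.75, type = 7)), 3.25)
  x <- rbind(c(1, 2, 3, 4, 0), c(10, 20, 30, 40, 0))
  out <- upper_quartile_normalize(toy_counts(x))
  expect_equal(out$normalized, "upper_quartile")
  dense <- as.matrix(out$counts)
  divisors <- c(3.25, 32.5)
  expected <- x / divisors * median(divisors)
  expect_equal(dense, expected, ignore_attr = TRUE, tolerance = 1e-12)
  # proportional cells land on a common scale: normalized rows coincide
  expect_equal(unname(dense[1, ]), unname(dense[2, ]))

  # single-cell matrix: median of divisors is the divisor, row sum preserved
  one <- upper_quartile_normalize(toy_counts(matrix(c(1, 2, 3, 4), nrow = 1)))
  expect_equal(sum(as.matrix(one$counts)), 10)

  expect_error(upper_quartile_normalize(toy_counts(rbind(c(1, 1), c(0, 0)))),
    "no nonzero")
})
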