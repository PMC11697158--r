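test_that("dense TSV and MTX readers round-trip counts exactly", {
  x <- toy_counts()
  d <- withr::local_tempdir()

  write_counts(x, file.path(d, "dense.tsv"), format = "dense_tsv")
  y <- read_counts(file.path(d, "dense.tsv"), format = "dense_tsv")
  expect_identical(dim(y), c(10L, 6L))
  expect_equal(as.matrix(y$counts), as.matrix(x$counts))

  write_counts(x, file.path(d, "mtx"), format = "mtx")
  z <- read_counts(file.path(d, "mtx"), format = "mtx")
  expect_equal(as.matrix(z$counts), as.matrix(x$counts))
  expect_equal(z$cell_meta$cell_type, x$cell_meta$cell_type)
})

test_that("a 3-gene x 2-cell dense TSV yields the declared shape", {
  d <- withr::local_tempdir()
  writeLines(c("gene\tc1\tc2", "g1\t1\t0", "g2\t2\t3", "g3\t0\t1"),
             file.path(d, "m.tsv"))
  x <- read_counts(file.path(d, "m.tsv"), format = "dense_tsv")
  expect_identical(dim(x), c(3L, 2L))
})

test_that("MTX triplet with mismatched gene list is rejected", {
  x <- toy_counts(n_genes = 5, n_cells = 3)
  d <- withr::local_tempdir()
  write_counts(x, file.path(d, "mtx"), format = "mtx")
  writeLines(sprintf("G%02d", 1:4), file.path(d, "mtx", "genes.tsv"))
  expect_error(read_counts(file.path(d, "mtx"), format = "mtx"),
               "format error")
})

test_that("malformed counts are rejected with context", {
  m <- matrix(c(1, -1, 0, 2), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(sc_counts(m), "non-negative")
  m2 <- matrix(1, 2, 2, dimnames = list(c("g1", "g1"), c("c1", "c2")))
  expect_error(sc_counts(m2), "duplicate gene id")
})

test_that("QC filter applies the documented default thresholds", {
  f <- formals(qc_filter)
  expect_equal(f$min_genes_per_cell, 200)
  expect_equal(f$min_cells_per_gene, 3)
  expect_equal(f$max_mito_frac, 0.20)
})

test_that("QC removes high-mito cells, sparse genes and empty cells", {
  # 10 genes x 5 cells: cell c05 has 23% mitochondrial counts, gene G10
  # is detected in cells c01 and c05 only -> expect a 9 x 4 result.
  m <- matrix(0, 10, 5,
              dimnames = list(c("MT-01", sprintf("G%02d", 2:10)),
                              sprintf("c%02d", 1:5)))
  m[2:9, 1:4] <- 1                      # broad expression
  m["MT-01", 1:4] <- 1                  # mito fraction 1/10 in c01..c04
  m["MT-01", 5] <- 3                    # 3 of 13 counts are mito (23%)
  m[2:9, 5] <- 1; m["G09", 5] <- 2
  m["G10", c(1, 5)] <- 1
  x <- sc_counts(m)
  out <- qc_filter(x, min_genes_per_cell = 3, min_cells_per_gene = 3,
                   max_mito_frac = 0.20)
  expect_identical(dim(out), c(9L, 4L))
  expect_false("c05" %in% colnames(out$counts))
  expect_false("G10" %in% rownames(out$counts))

  # a zero-count cell is always removed
  m2 <- m; m2[, 2] <- 0
  out2 <- qc_filter(sc_counts(m2), min_genes_per_cell = 0,
                    min_cells_per_gene = 0)
  expect_false("c02" %in% colnames(out2$counts))
})

test_that("QC filtering is idempotent", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rbinom(30 * 40, 3, 0.15), 30, 40,
                dimnames = list(c("MT-01", sprintf("G%02d", 2:30)),
                                sprintf("c%02d", 1:40)))
    x <- sc_counts(m)
    once <- tryCatch(qc_filter(x, min_genes_per_cell = 2),
                     error = function(e) NULL)
    if (is.null(once)) next
    twice <- qc_filter(once, min_genes_per_cell = 2)
    expect_identical(as.matrix(twice$counts), as.matrix(once$counts))
  }
})

test_that("log-normalisation follows the closed form", {
  m <- matrix(0, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  m["g1", "c1"] <- 10                      # single expressed gene
  m[, "c2"] <- c(1, 1, 2)
  ln <- lognorm(sc_counts(m), scale_factor = 1e4)
  expect_equal(ln$values["g1", "c1"], log(1 + 1e4))

  ln2 <- lognorm(sc_counts(m), scale_factor = 4)
  expect_equal(as.numeric(ln2$values[, "c2"]), log(c(2, 2, 3)))

  m[, "c1"] <- 0
  expect_error(lognorm(sc_counts(m)), "zero-total")
})

test_that("log-normalisation is depth-invariant and monotone within a cell", {
  x <- toy_counts(seed = 7)
  ln <- lognorm(x)
  m2 <- as.matrix(x$counts); m2[, 2] <- m2[, 2] * 2
  ln2 <- lognorm(sc_counts(m2, x$cell_meta))
  expect_equal(as.numeric(ln2$values[, 2]), as.numeric(ln$values[, 2]))

  v <- as.matrix(ln$values)[, 1]
  cnt <- as.matrix(x$counts)[, 1]
  ord <- order(cnt)
  expect_true(all(diff(v[ord]) >= 0))

  # pre-log totals equal the scale factor for every cell
  totals <- colSums(expm1(as.matrix(ln$values)))
  expect_equal(unname(totals), rep(1e4, ncol(ln$values)), tolerance = 1e-6)
})

test_that("a simulated cohort round-trips through the exchange layout", {
  sim <- simulate_cohort(small_config(seed = 3))
  d <- withr::local_tempdir()
  write_cohort(sim, d)
  p1 <- names(sim$matrices)[1]
  back <- read_counts(file.path(d, p1), format = "mtx")
  expect_equal(as.matrix(back$counts), as.matrix(sim$matrices[[p1]]$counts))
  expect_identical(
    read_gene_list(file.path(d, "seeds_multi_evidence.txt")),
    sim$seed_sets[[1]]$genes)
  truth <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(truth$program_genes), sort(sim$truth$program_genes))
})

test_that("gene lists skip comments, blanks and duplicates", {
  f <- withr::local_tempfile()
  writeLines(c("# header", "TP53", "", "KRT8 # trailing", "TP53", "VIM"), f)
  expect_identical(read_gene_list(f), c("TP53", "KRT8", "VIM"))
})
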