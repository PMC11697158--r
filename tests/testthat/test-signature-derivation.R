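make_programs <- function(fp, top_m = 3) {
  members <- lapply(seq_len(ncol(fp)), function(j) {
    rownames(fp)[order(-fp[, j], rownames(fp))][seq_len(top_m)]
  })
  structure(list(footprint = fp, members = members, degenerate_z = FALSE,
                 top_m = top_m), class = "archetype_programs")
}

test_that("program scoring saturates when seeds occupy the top ranks", {
  set.seed(31)
  fp <- matrix(rnorm(50 * 2), 50, 2,
               dimnames = list(sprintf("g%02d", 1:50), NULL))
  seeds <- gene_set("s", c("g01", "g02", "g03"))
  fp[seeds$genes, 1] <- 100 + 1:3     # exactly the top ranks of archetype 1
  sc <- score_programs(list(p1 = make_programs(fp)), list(seeds),
                       r_max = 50)
  expect_equal(sc$combined[1], 1)
  expect_lt(sc$combined[2], 1)
})

test_that("random footprints give a null combined score near one half", {
  set.seed(32)
  fp <- matrix(rnorm(1000 * 500), 1000, 500,
               dimnames = list(sprintf("g%04d", 1:1000), NULL))
  seeds <- gene_set("s", sample(rownames(fp), 20))
  sc <- score_programs(list(p1 = make_programs(fp)), list(seeds),
                       r_max = 1000)
  expect_equal(mean(sc$combined), 0.5, tolerance = 0.02)
})

test_that("archetype selection keeps the per-patient top quantile", {
  sc <- data.frame(patient = rep("p1", 8), archetype = 1:8,
                   combined = (1:8) / 10)
  out <- select_archetypes(sc, top_quantile = 0.25)
  expect_equal(sum(out$selected), 2L)
  expect_equal(out$archetype[out$selected], 7:8)

  tied <- data.frame(patient = rep("p1", 5), archetype = 1:5,
                     combined = rep(0.4, 5))
  expect_warning(out2 <- select_archetypes(tied), "tied")
  expect_true(all(out2$selected))
})

test_that("gene frequencies count archetype memberships", {
  ft <- gene_frequency(list(c("A", "B"), c("B", "C"), "B"))
  expect_equal(ft$gene, c("B", "A", "C"))
  expect_equal(ft$count, c(3L, 1L, 1L))
  expect_false("D" %in% ft$gene)
})

test_that("knee threshold finds the cliff and honours overrides", {
  ft <- gene_frequency(as.list(rep(letters[1:7],
                                   times = c(100, 98, 96, 94, 10, 9, 8))))
  # wide cliff between 94 and 10: knee sits at the top of the cliff
  expect_equal(as.integer(knee_threshold(ft)), 94L)
  expect_equal(as.integer(knee_threshold(ft)), knee_oracle(ft$count))

  lin <- gene_frequency(as.list(rep(letters[1:5], times = 5:1)))
  thr <- knee_threshold(lin)
  expect_true(attr(thr, "degenerate"))
  expect_equal(as.integer(thr), 1L)

  expect_equal(as.integer(knee_threshold(ft, override = 25)), 25L)
})

test_that("knee threshold equals a brute-force distance search", {
  set.seed(33)
  for (rep in 1:30) {
    counts <- sample(1:50, sample(6:30, 1), replace = TRUE)
    if (length(unique(counts)) < 3) next
    ft <- structure(data.frame(gene = sprintf("g%03d", seq_along(counts)),
                               count = sort(counts, decreasing = TRUE)),
                    class = c("frequency_table", "data.frame"))
    thr <- knee_threshold(ft)
    # the oracle replicates the distinct-spectrum search; a linear
    # spectrum routes to the density-aware fallback instead
    if (!attr(thr, "degenerate") && !is.na(attr(thr, "knee_index"))) {
      expect_equal(as.integer(thr), knee_oracle(counts))
    }
  }
})

test_that("an integer-complete spectrum falls back to the density knee", {
  # 40 genes at counts 37..41 (a dense head) plus a tail occupying every
  # integer count 1..36: the distinct spectrum is exactly linear, but
  # the table is far from featureless
  counts <- c(rep(37:41, each = 8), rep(1:36, times = c(rep(30, 12),
                                                        rep(3, 12),
                                                        rep(1, 12))))
  ft <- structure(data.frame(gene = sprintf("g%04d", seq_along(counts)),
                             count = sort(counts, decreasing = TRUE)),
                  class = c("frequency_table", "data.frame"))
  thr <- knee_threshold(ft)
  expect_false(attr(thr, "degenerate"))
  expect_gte(as.integer(thr), 25)   # cuts above the dense tail
})

test_that("core signatures respect the threshold and ordering", {
  ft <- gene_frequency(list(c("A", "B"), c("B", "C"), "B"))
  expect_equal(unclass(core_signature(ft, 1)), c("B", "A", "C"),
               ignore_attr = TRUE)
  expect_equal(unclass(core_signature(ft, 2)), "B", ignore_attr = TRUE)
  expect_error(core_signature(ft, 10), "threshold")
})

test_that("specificity profiles follow hand arithmetic", {
  # 4 genes x 8 cells, one tumour, 4 cell types of 2 cells
  types <- rep(c("epithelial", "fibroblast", "immune", "endothelial"),
               each = 2)
  m <- matrix(0, 4, 8, dimnames = list(paste0("g", 1:4), paste0("c", 1:8)))
  m["g1", types == "epithelial"] <- 2          # epithelial-exclusive
  m["g2", ] <- 1                                # uniform
  m["g3", ] <- rep(c(2, 1, 1, 0), each = 2)     # graded means
  m["g4", types == "fibroblast"] <- 3
  ln <- structure(list(values = Matrix::Matrix(m, sparse = TRUE),
                       cell_meta = data.frame(cell_id = colnames(m),
                                              patient_id = "t1",
                                              cell_type = types,
                                              stringsAsFactors = FALSE)),
                  class = "lognorm_matrix")
  sm <- specificity_matrix(ln, rownames(m), k_clusters = 2)
  S <- sm$specificity
  expect_equal(unname(S["g1", "epithelial"]), 1)
  expect_equal(sum(S["g1", ]), 1)
  expect_equal(unname(S["g2", ]), rep(0.25, 4))
  expect_equal(unname(S["g3", c("epithelial", "fibroblast", "immune",
                                "endothelial")]),
               c(0.5, 0.25, 0.25, 0))
  expect_true(all(abs(rowSums(S) - 1) < 1e-9))
})

test_that("refinement splits the core along cell-type specific clusters", {
  set.seed(34)
  types <- rep(c("epithelial", "fibroblast"), each = 10)
  genes <- sprintf("g%02d", 1:20)
  m <- matrix(abs(rnorm(20 * 20, 0.2, 0.05)), 20, 20,
              dimnames = list(genes, paste0("c", 1:20)))
  m[1:10, types == "epithelial"] <- m[1:10, types == "epithelial"] + 3
  m[11:20, types == "fibroblast"] <- m[11:20, types == "fibroblast"] + 3
  ln <- structure(list(values = Matrix::Matrix(m, sparse = TRUE),
                       cell_meta = data.frame(cell_id = colnames(m),
                                              patient_id = "t1",
                                              cell_type = types,
                                              stringsAsFactors = FALSE)),
                  class = "lognorm_matrix")
  core <- metasig:::new_signature(genes, "core")
  sm <- specificity_matrix(ln, genes, k_clusters = 2)
  spl <- refine_signature(core, sm, target = "epithelial")
  expect_setequal(unclass(spl$refined), genes[1:10])
  expect_setequal(unclass(spl$residual), genes[11:20])
  # partition invariants
  expect_setequal(c(unclass(spl$refined), unclass(spl$residual)),
                  unclass(core))
  expect_length(intersect(spl$refined, spl$residual), 0)
  expect_error(refine_signature(core, sm, target = "absent"), "absent")
})

test_that("packaged signature fixtures carry the published split sizes", {
  refined <- packaged_signature("refined")
  residual <- packaged_signature("residual")
  core <- packaged_signature("core")
  expect_length(refined, 177)
  expect_length(residual, 109)
  expect_length(core, 286)
  expect_length(intersect(refined, residual), 0)
  expect_setequal(unclass(core), c(unclass(refined), unclass(residual)))
})
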