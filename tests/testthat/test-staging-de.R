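test_that("staging reproduces the 20/60/20 split on untied scores", {
  s <- setNames((1:10) / 10, paste0("c", 1:10))
  st <- assign_stages(s)
  expect_equal(st$category[order(st$score)],
               c("low", "low", rep("mid", 6), "high", "high"))
  expect_equal(formals(assign_stages)$n_bins, 16)

  set.seed(41)
  s2 <- setNames(runif(503), paste0("c", 1:503))
  st2 <- assign_stages(s2)
  tab <- table(st2$category)
  expect_lte(abs(tab[["low"]] - round(503 * 0.2)), 1)
  expect_lte(abs(tab[["high"]] - round(503 * 0.2)), 1)
})

test_that("stage categories are monotone in score and bins equal width", {
  set.seed(42)
  s <- setNames(rbeta(200, 2, 5), paste0("c", 1:200))
  st <- assign_stages(s, n_bins = 16)
  expect_gte(min(st$score[st$category == "high"]),
             max(st$score[st$category == "mid"]))
  expect_gte(min(st$score[st$category == "mid"]),
             max(st$score[st$category == "low"]))
  expect_true(all(st$bin %in% 1:16))
  # equal-width binning: bin index recomputable from the breaks
  breaks <- seq(min(s), max(s), length.out = 17)
  expect_equal(st$bin, findInterval(st$score, breaks,
                                    rightmost.closed = TRUE))
})

test_that("all-equal scores collapse to mid with a degeneracy flag", {
  st <- assign_stages(setNames(rep(0.5, 20), paste0("c", 1:20)))
  expect_true(all(st$category == "mid"))
  expect_true(attr(st, "degenerate"))
})

test_that("pseudobulk sums counts and conserves totals", {
  x <- toy_counts(n_genes = 4, n_cells = 6, mito_first = FALSE)
  st <- data.frame(cell_id = colnames(x$counts),
                   score = c(.1, .1, .5, .5, .9, .9),
                   bin = 1L,
                   category = c("low", "low", "mid", "mid", "high", "high"),
                   stringsAsFactors = FALSE)
  pb <- pseudobulk(x, st, require_replicates = FALSE)
  expect_equal(sum(pb$counts), sum(x$counts))
  m <- as.matrix(x$counts)
  expect_equal(unname(pb$counts[, pb$meta$category == "high"]),
               unname(m[, 5] + m[, 6]))

  # counts all one, ten high cells in one sample -> pseudobulk of 10
  m1 <- matrix(1, 3, 10, dimnames = list(paste0("g", 1:3),
                                         paste0("c", 1:10)))
  x1 <- sc_counts(m1, data.frame(cell_id = colnames(m1),
                                 sample_id = "s1",
                                 stringsAsFactors = FALSE))
  st1 <- data.frame(cell_id = colnames(m1), score = 1, bin = 1L,
                    category = "high", stringsAsFactors = FALSE)
  pb1 <- pseudobulk(x1, st1, require_replicates = FALSE)
  expect_equal(unname(pb1$counts[, 1]), rep(10, 3))

  # replicate requirement names the offending category
  expect_error(pseudobulk(x1, st1), "high")
})

test_that("two samples by two categories aggregate as hand-checked", {
  m <- matrix(1:16, 4, 4, dimnames = list(paste0("g", 1:4),
                                          paste0("c", 1:4)))
  x <- sc_counts(m, data.frame(cell_id = colnames(m),
                               sample_id = c("s1", "s1", "s2", "s2"),
                               stringsAsFactors = FALSE))
  st <- data.frame(cell_id = colnames(m), score = c(0, 1, 0, 1), bin = 1L,
                   category = c("low", "high", "low", "high"),
                   stringsAsFactors = FALSE)
  pb <- pseudobulk(x, st)
  expect_equal(unname(pb$counts[, pb$meta$sample == "s1" &
                                  pb$meta$category == "low"]), c(1, 2, 3, 4))
  expect_equal(unname(pb$counts[, pb$meta$sample == "s2" &
                                  pb$meta$category == "high"]),
               c(13, 14, 15, 16))
})

test_that("differential expression handles identical groups and adjusts p", {
  counts <- matrix(rep(c(100, 50, 10), 4), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  pb <- structure(list(counts = counts,
                       meta = data.frame(sample = paste0("s", 1:4),
                                         category = c("high", "high",
                                                      "low", "low"))),
                  class = "pseudobulk_matrix")
  de <- pseudobulk_de(pb)
  expect_equal(de$log2_fc, rep(0, 3))
  expect_equal(de$p, rep(1, 3))
  expect_true(all(de$q >= de$p - 1e-12))
  expect_true(all(de$q >= 0 & de$q <= 1))

  # a single tested gene keeps q equal to p
  pb1 <- pb; pb1$counts <- pb$counts[1, , drop = FALSE]
  set.seed(43)
  pb1$counts[1, ] <- c(200, 220, 35, 40)
  de1 <- pseudobulk_de(pb1)
  expect_equal(de1$q, de1$p)
})

test_that("planted fold changes are recovered by pseudobulk DE", {
  set.seed(44)
  n_gene <- 600; fold <- 4
  de_idx <- 1:12      # 2% DE so CPM composition bias stays negligible
  mu <- rexp(n_gene, 1 / 200)
  mk <- function(group) {
    vapply(1:6, function(i) {
      m <- mu
      if (group == "high") m[de_idx] <- m[de_idx] * fold
      rnbinom(n_gene, mu = m, size = 20)
    }, numeric(n_gene))
  }
  counts <- cbind(mk("high"), mk("low"))
  dimnames(counts) <- list(sprintf("g%03d", 1:n_gene), paste0("s", 1:12))
  pb <- structure(list(counts = counts,
                       meta = data.frame(sample = paste0("s", 1:12),
                                         category = rep(c("high", "low"),
                                                        each = 6))),
                  class = "pseudobulk_matrix")
  de <- pseudobulk_de(pb)
  planted <- de[de_idx, ]
  expect_gte(mean(planted$q < 0.05), 0.9)
  expect_true(median(planted$log2_fc) > 1.4 & median(planted$log2_fc) < 2.6)
})
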