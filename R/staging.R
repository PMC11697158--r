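#' Assign metastatic stages to cells from signature scores
#'
#' Discretises per-cell scores into `n_bins` equal-width bins over the
#' observed range (half-open intervals, last bin closed) and into
#' low/mid/high categories by empirical quantiles: the bottom `q_low`
#' fraction is low, the top `1 - q_high` fraction is high, the rest mid.
#' Cells tied at a category boundary are resolved toward mid, so category
#' sizes match the target proportions to within the tie structure
#' (exactly, +/- 1 cell, for untied scores).
#'
#' @param scores named numeric vector of per-cell scores (from
#'   [set_score()]).
#' @param n_bins number of equal-width bins (default 16).
#' @param q_low,q_high category quantiles (defaults 0.2 and 0.8 give the
#'   20/60/20 split).
#' @return data.frame of class `stage_assignment` (cell_id, score, bin,
#'   category) with attribute `degenerate` when all scores tie.
#' @export
assign_stages <- function(scores, n_bins = 16, q_low = 0.2, q_high = 0.8) {
  n <- length(scores)
  if (n < 10L) stop("need at least 10 cells")
  if (!(q_low > 0 && q_low < q_high && q_high < 1)) {
    stop("require 0 < q_low < q_high < 1")
  }
  s <- as.numeric(scores)
  degenerate <- diff(range(s)) == 0
  if (degenerate) {
    bin <- rep(1L, n)
    category <- rep("mid", n)
  } else {
    breaks <- seq(min(s), max(s), length.out = n_bins + 1L)
    bin <- findInterval(s, breaks, rightmost.closed = TRUE)
    v <- sort(s)
    n_low <- round(n * q_low)
    n_high <- round(n * (1 - q_high))
    category <- rep("mid", n)
    if (n_low > 0L) {
      c_lo <- v[n_low]
      low <- s < c_lo
      tied <- s == c_lo
      if (sum(low) + sum(tied) <= n_low) low <- low | tied
      category[low] <- "low"
    }
    if (n_high > 0L) {
      c_hi <- v[n - n_high + 1L]
      high <- s > c_hi
      tied <- s == c_hi
      if (sum(high) + sum(tied) <= n_high) high <- high | tied
      category[high] <- "high"
    }
  }
  out <- data.frame(cell_id = names(scores) %||% as.character(seq_len(n)),
                    score = s, bin = as.integer(bin), category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("stage_assignment", "data.frame")
  attr(out, "degenerate") <- degenerate
  if (!degenerate) {
    # partition must be monotone in score
    stopifnot(
      suppressWarnings(min(out$score[out$category == "high"])) >=
        suppressWarnings(max(out$score[out$category == "mid"])) ||
        !any(out$category == "high") || !any(out$category == "mid"),
      suppressWarnings(min(out$score[out$category == "mid"])) >=
        suppressWarnings(max(out$score[out$category == "low"])) ||
        !any(out$category == "mid") || !any(out$category == "low"))
  }
  out
}

#' Pseudobulk aggregation by sample and stage category
#'
#' Sums raw counts over cells within each (sample, category) pair,
#' producing sample-level expression profiles suitable for
#' between-category differential expression. Totals are conserved: the
#' pseudobulk grand total equals the contributing cells' grand total.
#'
#' @param x an [sc_counts] (or list of them, concatenated by sample).
#' @param stages a [assign_stages()] table covering the cells of `x`.
#' @param group_by metadata column identifying samples.
#' @param require_replicates error when a category is present in fewer
#'   than 2 samples (needed downstream by [pseudobulk_de()]).
#' @return object of class `pseudobulk_matrix`: integer `counts` (genes x
#'   pseudobulk samples) and `meta` (sample, category).
#' @export
pseudobulk <- function(x, stages, group_by = "sample_id",
                       require_replicates = TRUE) {
  if (inherits(x, "sc_counts")) x <- list(x)
  cat_of <- stages$category
  names(cat_of) <- stages$cell_id
  pieces <- list()
  for (xi in x) {
    m <- xi$counts
    meta <- xi$cell_meta
    if (is.null(meta[[group_by]])) stop("cell_meta lacks ", group_by)
    cells <- colnames(m)[colnames(m) %in% names(cat_of)]
    m <- m[, cells, drop = FALSE]
    grp <- paste(meta[[group_by]][match(cells, meta$cell_id)],
                 cat_of[cells], sep = "\r")
    for (g in unique(grp)) {
      sums <- Matrix::rowSums(m[, grp == g, drop = FALSE])
      pieces[[g]] <- if (is.null(pieces[[g]])) sums else pieces[[g]] + sums
    }
  }
  if (length(pieces) == 0L) stop("no cells matched the stage table")
  genes <- names(pieces[[1L]])
  counts <- vapply(pieces, function(p) p[genes], numeric(length(genes)))
  parts <- strsplit(names(pieces), "\r", fixed = TRUE)
  meta <- data.frame(sample = vapply(parts, `[`, "", 1L),
                     category = vapply(parts, `[`, "", 2L),
                     stringsAsFactors = FALSE)
  colnames(counts) <- paste(meta$sample, meta$category, sep = ".")
  if (require_replicates) {
    for (ct in unique(meta$category)) {
      if (length(unique(meta$sample[meta$category == ct])) < 2L) {
        stop("category '", ct, "' is present in fewer than 2 samples")
      }
    }
  }
  structure(list(counts = counts, meta = meta),
            class = "pseudobulk_matrix")
}

#' Pseudobulk differential expression (high vs low)
#'
#' Per gene, a Welch two-sample t-test on log2-CPM(+1) values across
#' pseudobulk samples of the two contrasted categories; the log2 fold
#' change is the mean difference, and p-values are Benjamini-Hochberg
#' adjusted across genes. Genes with zero variance on both sides and
#' equal means get p = 1.
#'
#' @param pb a [pseudobulk()] matrix.
#' @param contrast character pair, numerator first (default high vs low).
#' @return data.frame of class `de_result`: gene, log2_fc, statistic, p, q.
#' @export
pseudobulk_de <- function(pb, contrast = c("high", "low")) {
  stopifnot(inherits(pb, "pseudobulk_matrix"), length(contrast) == 2L)
  keep <- pb$meta$category %in% contrast
  counts <- pb$counts[, keep, drop = FALSE]
  cat <- pb$meta$category[keep]
  if (sum(cat == contrast[1L]) < 2L || sum(cat == contrast[2L]) < 2L) {
    stop("need >= 2 pseudobulk samples per side")
  }
  lcpm <- log2(1 + 1e6 * sweep(counts, 2L, colSums(counts), "/"))
  a <- lcpm[, cat == contrast[1L], drop = FALSE]
  b <- lcpm[, cat == contrast[2L], drop = FALSE]
  res <- t(vapply(seq_len(nrow(lcpm)), function(i) {
    xi <- a[i, ]; yi <- b[i, ]
    fc <- mean(xi) - mean(yi)
    if (sd(xi) == 0 && sd(yi) == 0) {
      if (fc == 0) c(fc, 0, 1) else c(fc, sign(fc) * Inf, 0)
    } else {
      tt <- t.test(xi, yi, var.equal = FALSE)
      c(fc, unname(tt$statistic), tt$p.value)
    }
  }, numeric(3)))
  out <- data.frame(gene = rownames(lcpm), log2_fc = res[, 1L],
                    statistic = res[, 2L], p = res[, 3L],
                    q = p.adjust(res[, 3L], method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}
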