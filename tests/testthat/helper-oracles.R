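# Independent oracles and small fixture builders used across tests.

# Brute-force Mann-Whitney U score for one unit: counts, over all
# (signature, complement) gene pairs, how often the signature gene is the
# lower-expressed one (ties 0.5). Equivalent to the rank-sum formulation
# when the rank cap is inactive; deliberately avoids rank().
mw_score_oracle <- function(values, sig_idx, r_max) {
  other <- setdiff(seq_along(values), sig_idx)
  u <- 0
  for (s in sig_idx) {
    for (c in other) {
      if (values[s] < values[c]) u <- u + 1
      else if (values[s] == values[c]) u <- u + 0.5
    }
  }
  n_g <- length(sig_idx)
  max(0, 1 - u / (n_g * r_max))
}

# Brute-force knee: maximum perpendicular distance over the distinct
# sorted counts, by explicit loop over candidate points.
knee_oracle <- function(counts) {
  cs <- sort(unique(counts), decreasing = TRUE)
  L <- length(cs)
  xs <- (seq_len(L) - 1) / (L - 1)
  ys <- (cs - min(cs)) / diff(range(cs))
  best <- -1; best_j <- NA
  for (j in seq_len(L)) {
    # distance from point j to the line through (0, ys[1]) and (1, ys[L])
    num <- abs((ys[L] - ys[1]) * xs[j] - 1 * (ys[j] - ys[1]))
    d <- num / sqrt(1 + (ys[L] - ys[1])^2)
    if (d > best) { best <- d; best_j <- j }
  }
  cs[best_j]
}

# Exact one-sided rank-sum p-value by enumeration of all assignments.
ranksum_p_oracle <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(all_v), n)
  w_obs <- sum(rank(all_v)[seq_len(n)])
  count <- 0
  for (j in seq_len(ncol(idx))) {
    if (sum(rank(all_v)[idx[, j]]) >= w_obs) count <- count + 1
  }
  count / ncol(idx)
}

# Tiny deterministic count matrix with metadata.
toy_counts <- function(n_genes = 10, n_cells = 6, seed = 42,
                       mito_first = TRUE) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells)
  g <- sprintf("G%02d", seq_len(n_genes))
  if (mito_first) g[1] <- "MT-01"
  dimnames(m) <- list(g, sprintf("c%02d", seq_len(n_cells)))
  sc_counts(m, data.frame(cell_id = colnames(m), patient_id = "P1",
                          sample_id = "P1", cancer_type = "CT1",
                          cell_type = rep(c("epithelial", "fibroblast"),
                                          length.out = n_cells),
                          stringsAsFactors = FALSE))
}

# Small simulation config for fast generator tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_patients = 2, n_cancer_types = 2, cells_per_patient = 300,
             n_genes = 420, program_size = 60, seed = seed, ...)
}
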