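#' Configuration for the synthetic pan-cancer cohort
#'
#' Defaults describe the reference study conditions used throughout the
#' package's validation: 12 patients over 4 cancer types, ~1,500 cells
#' per patient, 2,000 genes, a planted 150-gene metastatic program at a
#' log2 effect of 2 expressed by 30% of the relevant cells with a
#' continuous per-cell intensity (uniform on [0,1]), and moderately
#' overdispersed negative-binomial counts.
#'
#' The planted program has two halves: an epithelial-specific half
#' expressed by a subset of epithelial cells ("program cells") and a
#' stromal half expressed by a matching subset of fibroblasts, mirroring
#' a signature that mixes cancer-cell and microenvironment genes. Cell
#' identity is encoded by lineage expression blocks shared between pairs
#' of cell types; the first 20 genes carry an `MT-` prefix so
#' mitochondrial QC is exercisable.
#'
#' @param n_patients,n_cancer_types,cells_per_patient,n_genes cohort
#'   dimensions.
#' @param cell_type_fractions named proportions summing to 1; must
#'   include "epithelial" and "fibroblast".
#' @param program_size number of planted program genes (split in half).
#' @param program_cell_fraction fraction of epithelial (resp. fibroblast)
#'   cells expressing the program.
#' @param program_log2_effect log2 fold increase of program genes in
#'   program cells at full intensity.
#' @param nb_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param seed integer seed; identical configs generate identical data.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 12L, n_cancer_types = 4L,
                       cells_per_patient = 1500L, n_genes = 2000L,
                       cell_type_fractions = c(epithelial = 0.5,
                                               fibroblast = 0.2,
                                               immune = 0.2,
                                               endothelial = 0.1),
                       program_size = 150L, program_cell_fraction = 0.3,
                       program_log2_effect = 2, nb_dispersion = 2,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_cancer_types = as.integer(n_cancer_types),
              cells_per_patient = as.integer(cells_per_patient),
              n_genes = as.integer(n_genes),
              cell_type_fractions = cell_type_fractions,
              program_size = as.integer(program_size),
              program_cell_fraction = program_cell_fraction,
              program_log2_effect = program_log2_effect,
              nb_dispersion = nb_dispersion,
              seed = as.integer(seed))
  for (f in c("n_patients", "n_cancer_types", "cells_per_patient",
              "n_genes", "program_size")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("invalid sim_config field '", f, "': must be a positive count")
    }
  }
  fr <- cfg$cell_type_fractions
  if (is.null(names(fr)) || any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("invalid sim_config field 'cell_type_fractions': named ",
         "proportions must sum to 1")
  }
  if (!all(c("epithelial", "fibroblast") %in% names(fr))) {
    stop("invalid sim_config field 'cell_type_fractions': must include ",
         "'epithelial' and 'fibroblast'")
  }
  if (cfg$program_size >= cfg$n_genes) {
    stop("invalid sim_config field 'program_size': must be < n_genes")
  }
  if (cfg$n_genes < 180L + cfg$program_size + 60L) {
    stop("invalid sim_config field 'n_genes': too small for the gene ",
         "layout (need >= ", 180L + cfg$program_size + 60L, ")")
  }
  if (cfg$program_cell_fraction <= 0 || cfg$program_cell_fraction > 1) {
    stop("invalid sim_config field 'program_cell_fraction': must be in (0,1]")
  }
  if (!is.finite(cfg$program_log2_effect) || cfg$program_log2_effect < 0) {
    stop("invalid sim_config field 'program_log2_effect'")
  }
  if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion <= 0) {
    stop("invalid sim_config field 'nb_dispersion': must be positive")
  }
  structure(cfg, class = "sim_config")
}

# deterministic gene layout for a config
gene_layout <- function(cfg) {
  ng <- cfg$n_genes
  ids <- sprintf("G%04d", seq_len(ng))
  ids[1:20] <- sprintf("MT-%02d", 1:20)
  half1 <- ceiling(cfg$program_size / 2)
  half2 <- cfg$program_size - half1
  list(ids = ids,
       mt = 1:20,
       blockA = 21:60,        # epithelial + endothelial lineage
       blockB = 61:100,       # fibroblast + immune lineage
       blockC = 101:140,      # immune + endothelial lineage
       prog_epi = 141:(140 + half1),
       prog_str = (141 + half1):(140 + half1 + half2),
       background = (141 + cfg$program_size):ng)
}

#' Generate a multi-patient pan-cancer single-cell cohort
#'
#' Draws negative-binomial UMI counts per patient with log-normal gene
#' means, per-cell library-size factors, lineage expression blocks, a
#' mild cancer-type effect, and the planted two-half metastatic program
#' described in [sim_config()]. Also returns two seed gene lists (a
#' "multi-evidence" and a noisier "single-evidence" tier) that overlap
#' the planted program, emulating a literature-derived metastasis gene
#' resource.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrices` (one [sc_counts] per patient), `truth`
#'   (program_genes, epithelial_specific_genes, stromal_genes,
#'   program_cells, de_genes with planted log2 fold changes), and
#'   `seed_sets` (list of two [gene_set]s).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    lay <- gene_layout(cfg)
    ng <- cfg$n_genes
    nc <- cfg$cells_per_patient
    mu <- rlnorm(ng, meanlog = log(0.4), sdlog = 1.0)
    mu[lay$mt] <- mu[lay$mt] * 6
    # program genes moderately expressed so planted effects are observable
    mu[c(lay$prog_epi, lay$prog_str)] <-
      rlnorm(cfg$program_size, meanlog = log(1), sdlog = 0.3)
    ctypes <- sprintf("CT%d", seq_len(cfg$n_cancer_types))
    ct_genes <- lapply(ctypes, function(ct) {
      sample(lay$background, min(40L, length(lay$background)))
    })
    names(ct_genes) <- ctypes
    patient_ct <- rep(ctypes, length.out = cfg$n_patients)
    fr <- cfg$cell_type_fractions
    eff <- cfg$program_log2_effect

    matrices <- list()
    program_cells <- character(0)
    for (p in seq_len(cfg$n_patients)) {
      pid <- sprintf("P%02d", p)
      types <- sample(names(fr), nc, replace = TRUE, prob = fr)
      M <- matrix(mu, ng, nc)
      # lineage blocks are shared across three types each, so cell
      # identity is combinatorial and no block is exclusive to the cell
      # population carrying a planted program
      inA <- types %in% c("epithelial", "endothelial", "immune")
      M[lay$blockA, inA] <- M[lay$blockA, inA] * 3
      inB <- types %in% c("fibroblast", "immune", "endothelial")
      M[lay$blockB, inB] <- M[lay$blockB, inB] * 3
      inC <- types %in% c("epithelial", "fibroblast", "endothelial")
      M[lay$blockC, inC] <- M[lay$blockC, inC] * 3

      prog_e <- sample(which(types == "epithelial"),
                       round(cfg$program_cell_fraction *
                               sum(types == "epithelial")))
      prog_f <- which(types == "fibroblast")
      if (length(prog_e)) {
        u <- runif(length(prog_e))
        M[lay$prog_epi, prog_e] <-
          M[lay$prog_epi, prog_e] *
          rep(2^(eff * u), each = length(lay$prog_epi))
      }
      if (length(prog_f)) {
        # stromal half: constitutive expression in program fibroblasts at
        # the program's average intensity, E[2^(eff*U)] for U ~ Unif(0,1)
        mult <- if (eff > 0) (2^eff - 1) / (eff * log(2)) else 1
        M[lay$prog_str, prog_f] <- M[lay$prog_str, prog_f] * mult
      }
      ctg <- ct_genes[[patient_ct[p]]]
      M[ctg, ] <- M[ctg, ] * 1.5
      lib <- rlnorm(nc, 0, 0.3)
      M <- M * rep(lib, each = ng)
      counts <- matrix(rnbinom(length(M), size = cfg$nb_dispersion, mu = M),
                       ng, nc)
      cell_ids <- sprintf("%s_C%04d", pid, seq_len(nc))
      dimnames(counts) <- list(lay$ids, cell_ids)
      meta <- data.frame(cell_id = cell_ids, patient_id = pid,
                         sample_id = pid, cancer_type = patient_ct[p],
                         cell_type = types, stringsAsFactors = FALSE)
      prog_ids <- cell_ids[prog_e]
      program_cells <- c(program_cells, prog_ids)
      matrices[[pid]] <- sc_counts(counts, meta)
    }

    prog_genes <- lay$ids[c(lay$prog_epi, lay$prog_str)]
    non_prog <- lay$ids[lay$background]
    # seed lists cover tumour-cell and microenvironment metastasis genes
    # evenly, emulating a curated resource spanning both compartments
    pick_half <- function(n) c(sample(lay$ids[lay$prog_epi], n),
                               sample(lay$ids[lay$prog_str], n))
    seed_multi <- gene_set("multi_evidence",
                           c(pick_half(30L), sample(non_prog, 40L)),
                           tier = "multi-evidence")
    seed_single <- gene_set("single_evidence",
                            c(pick_half(30L),
                              sample(setdiff(non_prog, seed_multi$genes),
                                     140L)),
                            tier = "single-evidence")
    de <- rep(cfg$program_log2_effect, length(lay$prog_epi))
    names(de) <- lay$ids[lay$prog_epi]
    list(matrices = matrices,
         truth = list(
           program_genes = prog_genes,
           epithelial_specific_genes = lay$ids[lay$prog_epi],
           stromal_genes = lay$ids[lay$prog_str],
           program_cells = program_cells,
           de_genes = de),
         seed_sets = list(seed_multi, seed_single),
         config = cfg)
  })
}

#' Generate a bulk cohort with survival tied to a signature score
#'
#' Builds a samples x genes log-expression matrix in which the signature
#' genes share a per-sample latent factor (plus a tumour-vs-normal shift),
#' computes each sample's signature Z score from the generated data, and
#' draws exponential survival times with hazard
#' \eqn{\lambda_0 \exp(\beta \cdot score)}. Censoring is independent
#' exponential, calibrated so the expected censoring fraction under a
#' null signature equals `censor_rate`; `censor_rate = 0` yields events
#' everywhere. Clinical covariates (cancer type, purity, stage, age,
#' tissue) are populated; stage is weakly coupled to the latent factor.
#'
#' @param n_samples number of samples.
#' @param signature gene ids forming the signature.
#' @param beta log hazard ratio per unit score (finite).
#' @param censor_rate target censoring fraction in [0, 1).
#' @param seed RNG seed.
#' @param n_genes total gene universe (signature plus background).
#' @param n_cancer_types number of cancer types.
#' @param normal_fraction fraction of samples labelled normal tissue.
#' @param signature_strength loading of the latent factor on signature
#'   genes (log-expression units).
#' @param tumour_shift added to signature genes in tumour samples.
#' @param baseline_hazard exponential baseline rate.
#' @return list with `cohort` (a [bulk_cohort]) and `truth` (beta,
#'   per-sample scores used in the hazard).
#' @export
simulate_bulk_cohort <- function(n_samples, signature, beta,
                                 censor_rate = 0.25, seed = 1L,
                                 n_genes = 1000L, n_cancer_types = 4L,
                                 normal_fraction = 0, tumour_shift = 1,
                                 signature_strength = 0.8,
                                 baseline_hazard = 0.1) {
  if (!is.finite(beta)) stop("parameter error: beta must be finite")
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("parameter error: censor_rate must be in [0, 1)")
  }
  sig <- if (inherits(signature, "gene_set")) signature$genes
         else as.character(signature)
  with_seed(seed, {
    n_genes <- max(n_genes, length(sig) + 50L)
    genes <- c(sig, sprintf("BG%04d", seq_len(n_genes - length(sig))))
    mu_g <- rnorm(n_genes, 5, 1)
    z <- rnorm(n_samples)
    E <- matrix(rnorm(n_samples * n_genes), n_samples, n_genes)
    E <- sweep(E, 2L, mu_g, "+")
    tissue <- ifelse(runif(n_samples) < normal_fraction, "normal", "tumour")
    sig_idx <- seq_along(sig)
    E[, sig_idx] <- E[, sig_idx] + signature_strength * z
    E[tissue == "tumour", sig_idx] <-
      E[tissue == "tumour", sig_idx] + tumour_shift
    dimnames(E) <- list(sprintf("S%04d", seq_len(n_samples)), genes)
    late <- rbinom(n_samples, 1L, plogis(0.3 * z)) == 1L
    clinical <- data.frame(
      sample_id = rownames(E),
      time = 1, event = 1L,
      cancer_type = sample(sprintf("CT%d", seq_len(n_cancer_types)),
                           n_samples, replace = TRUE),
      purity = rbeta(n_samples, 5, 2),
      stage = ifelse(late, sample(3:4, n_samples, replace = TRUE),
                     sample(1:2, n_samples, replace = TRUE)),
      age = pmin(90, pmax(30, round(rnorm(n_samples, 65, 10)))),
      tissue = tissue, stringsAsFactors = FALSE)
    co <- bulk_cohort(E, clinical)
    score <- suppressWarnings(signature_zscore(co, sig))
    rate <- baseline_hazard * exp(beta * score)
    tt <- rexp(n_samples, rate)
    if (censor_rate > 0) {
      cc <- rexp(n_samples,
                 baseline_hazard * censor_rate / (1 - censor_rate))
      clinical$event <- as.integer(tt <= cc)
      clinical$time <- pmin(tt, cc)
    } else {
      clinical$event <- 1L
      clinical$time <- tt
    }
    list(cohort = bulk_cohort(E, clinical),
         truth = list(beta = beta, scores = score))
  })
}

#' Generate a spatial slide with an enriched invasive edge
#'
#' Lays a rectangular spot grid with three annotated regions (a central
#' tumour body, a surrounding invasive edge ring, and stroma), draws
#' negative-binomial counts, and inflates program-gene means by
#' `2^edge_effect` in edge spots (half the effect, on the log2 scale, in
#' the tumour body so regions order stroma < body < edge). With
#' `edge_effect = 0` the regions are exchangeable.
#'
#' @param grid integer pair (columns, rows), at least 10 x 10.
#' @param edge_effect log2 inflation of program genes at the edge.
#' @param seed RNG seed.
#' @param n_genes,program_size gene universe and planted program size.
#' @param nb_dispersion negative-binomial size.
#' @return list with `slide` (a [spatial_slide]) and `truth`
#'   (program_genes, region of every spot).
#' @export
simulate_spatial_slide <- function(grid = c(30, 30), edge_effect = 1.5,
                                   seed = 1L, n_genes = 400L,
                                   program_size = 80L, nb_dispersion = 2) {
  if (length(grid) != 2L || any(grid < 10)) {
    stop("parameter error: grid must be at least 10 x 10")
  }
  with_seed(seed, {
    g <- expand.grid(x = seq_len(grid[1L]), y = seq_len(grid[2L]))
    cx <- (grid[1L] + 1) / 2
    cy <- (grid[2L] + 1) / 2
    d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
    r_body <- 0.25 * min(grid)
    r_edge <- r_body + max(2, 0.08 * min(grid))
    region <- ifelse(d <= r_body, "tumour body",
                     ifelse(d <= r_edge, "invasive edge", "stroma"))
    ns <- nrow(g)
    genes <- sprintf("SG%04d", seq_len(n_genes))
    prog <- genes[seq_len(program_size)]
    mu <- rlnorm(n_genes, log(1), 1)
    mu[seq_len(program_size)] <- rlnorm(program_size, log(1.5), 0.3)
    M <- matrix(mu, n_genes, ns)
    pb <- region == "tumour body"
    pe <- region == "invasive edge"
    M[seq_len(program_size), pb] <-
      M[seq_len(program_size), pb] * 2^(edge_effect / 2)
    M[seq_len(program_size), pe] <-
      M[seq_len(program_size), pe] * 2^edge_effect
    counts <- matrix(rnbinom(length(M), size = nb_dispersion, mu = M),
                     n_genes, ns)
    spot_ids <- sprintf("spot%04d", seq_len(ns))
    dimnames(counts) <- list(genes, spot_ids)
    spots <- data.frame(spot_id = spot_ids, x = g$x, y = g$y,
                        region = region, stringsAsFactors = FALSE)
    list(slide = spatial_slide(spots, counts),
         truth = list(program_genes = prog,
                      region = setNames(region, spot_ids)))
  })
}

#' Generate a pseudotime expression panel with switching genes
#'
#' Each switch gene's on-probability follows a logistic curve in
#' pseudotime centred at its switch time t* with the given steepness and
#' direction; "on" cells draw log-expression well above the conventional
#' 0.2 binarisation cutoff, "off" cells below it. Non-switch (null)
#' genes have a constant on-probability independent of pseudotime.
#'
#' @param n_cells number of cells.
#' @param switch_spec data.frame with columns `gene`, `t0` in (0,1),
#'   `direction` ("on"/"off") and `steepness`.
#' @param n_null_genes number of pseudotime-independent genes.
#' @param seed RNG seed.
#' @return list with `expr` (genes x cells log-expression matrix),
#'   `pseudotime` (in [0,1]) and `truth` (switch_times, directions).
#' @export
simulate_pseudotime_panel <- function(n_cells = 500L, switch_spec,
                                      n_null_genes = 100L, seed = 1L) {
  stopifnot(is.data.frame(switch_spec),
            all(c("gene", "t0", "direction", "steepness") %in%
                  names(switch_spec)))
  if (any(switch_spec$t0 <= 0 | switch_spec$t0 >= 1)) {
    stop("parameter error: t0 must lie in (0, 1)")
  }
  with_seed(seed, {
    pt <- runif(n_cells)
    draw_expr <- function(state) {
      ifelse(state == 1L,
             pmax(0.3, rnorm(length(state), 1, 0.25)),
             pmax(0, rnorm(length(state), 0.05, 0.04)))
    }
    rows <- list()
    for (i in seq_len(nrow(switch_spec))) {
      sgn <- if (switch_spec$direction[i] == "on") 1 else -1
      p_on <- plogis(sgn * switch_spec$steepness[i] *
                       (pt - switch_spec$t0[i]))
      state <- rbinom(n_cells, 1L, p_on)
      rows[[switch_spec$gene[i]]] <- draw_expr(state)
    }
    for (j in seq_len(n_null_genes)) {
      p <- runif(1, 0.3, 0.7)
      state <- rbinom(n_cells, 1L, p)
      rows[[sprintf("NULL%03d", j)]] <- draw_expr(state)
    }
    expr <- do.call(rbind, rows)
    colnames(expr) <- sprintf("cell%04d", seq_len(n_cells))
    list(expr = expr, pseudotime = pt,
         truth = list(switch_times = setNames(switch_spec$t0,
                                              switch_spec$gene),
                      directions = setNames(switch_spec$direction,
                                            switch_spec$gene)))
  })
}
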