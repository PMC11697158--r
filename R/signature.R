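#' Score archetype programs against seed gene sets
#'
#' Each archetype's footprint profile (z-scored weighted mean expression
#' over all genes) is treated as the expression profile of one unit and
#' scored with [set_score()] against every seed set; the combined score is
#' the mean over seed sets. Archetypes rich in metastasis-associated seed
#' genes score near 1.
#'
#' @param programs named list (one element per patient) of
#'   `archetype_programs`.
#' @param seeds list of [gene_set]s (typically a single-evidence and a
#'   multi-evidence tier).
#' @param r_max rank cap passed to [set_score()]; the default matches the
#'   conventional program size so that seed genes outside an archetype's
#'   program contribute a constant penalty.
#' @return data.frame with columns patient, archetype, one score column
#'   per seed set, and `combined`.
#' @export
score_programs <- function(programs, seeds, r_max = 200) {
  if (inherits(seeds, "gene_set")) seeds <- list(seeds)
  if (is.null(names(programs))) {
    names(programs) <- sprintf("patient%02d", seq_along(programs))
  }
  rows <- lapply(names(programs), function(p) {
    fp <- programs[[p]]$footprint
    colnames(fp) <- sprintf("a%d", seq_len(ncol(fp)))
    per_set <- vapply(seeds, function(s) {
      as.numeric(set_score(fp, s, r_max = r_max))
    }, numeric(ncol(fp)))
    per_set <- matrix(per_set, nrow = ncol(fp))
    colnames(per_set) <- vapply(seeds, function(s) s$name, character(1))
    data.frame(patient = p, archetype = seq_len(ncol(fp)), per_set,
               combined = rowMeans(per_set), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select top-scoring archetypes within each patient
#'
#' Keeps archetypes whose combined seed score reaches the
#' `1 - top_quantile` quantile of scores within their patient. If all
#' scores within a patient tie, all archetypes are kept with a warning.
#'
#' @param scores output of [score_programs()].
#' @param top_quantile fraction of archetypes to target (default 0.25).
#' @return `scores` with an added logical column `selected`.
#' @export
select_archetypes <- function(scores, top_quantile = 0.25) {
  if (nrow(scores) < 4L) stop("need at least 4 archetypes to rank")
  sel <- logical(nrow(scores))
  for (p in unique(scores$patient)) {
    i <- scores$patient == p
    s <- scores$combined[i]
    if (diff(range(s)) == 0) {
      warning("all archetype scores tied for patient ", p,
              "; selecting all")
      sel[i] <- TRUE
    } else {
      sel[i] <- s >= quantile(s, 1 - top_quantile, type = 7)
    }
  }
  scores$selected <- sel
  scores
}

#' Gene frequency across selected archetype programs
#'
#' Counts, for every gene, the number of selected archetypes (pooled over
#' patients) whose member-gene programs contain it.
#'
#' @param member_lists list of character vectors, one per selected
#'   archetype (e.g. the `members` entries of `archetype_programs`).
#' @return object of class `frequency_table`: data.frame (gene, count)
#'   sorted by decreasing count then gene id, with attribute
#'   `n_archetypes`.
#' @export
gene_frequency <- function(member_lists) {
  if (length(member_lists) == 0L) stop("no selected archetypes")
  tab <- table(unlist(member_lists, use.names = FALSE))
  ft <- data.frame(gene = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  ft <- ft[order(-ft$count, ft$gene), , drop = FALSE]
  rownames(ft) <- NULL
  structure(ft, class = c("frequency_table", "data.frame"),
            n_archetypes = length(member_lists))
}

#' Knee-point threshold on an archetype-frequency table
#'
#' Finds the inflection of the count spectrum: the distinct count values
#' are sorted in decreasing order, both axes normalised to the unit
#' interval, and the threshold is the count at maximum perpendicular
#' distance from the chord joining the first and last point. Working on
#' distinct values keeps the knee at the top of the cliff separating
#' consistently recurring genes from the singleton tail, rather than being
#' dragged into the tail by its sheer length. When the spectrum is linear
#' because every integer count is occupied, the knee is taken on the
#' per-gene curve with a log-scaled index axis instead; a table whose
#' per-gene counts are themselves an arithmetic sequence is genuinely
#' featureless and is flagged degenerate with the minimum count returned.
#' An explicit `override` bypasses the search.
#'
#' @param ft a [gene_frequency()] table with at least 3 distinct counts.
#' @param override integer threshold to use verbatim (e.g. a cut taken
#'   from an external analysis), or NULL for the knee.
#' @return integer threshold with attributes `degenerate` and `knee_index`.
#' @export
knee_threshold <- function(ft, override = NULL) {
  if (!is.null(override)) {
    return(structure(as.integer(override), degenerate = FALSE,
                     knee_index = NA_integer_))
  }
  counts <- sort(unique(ft$count), decreasing = TRUE)
  if (length(ft$gene) < 3L) stop("need at least 3 genes")
  if (length(counts) < 3L) stop("need at least 3 distinct counts")
  k <- chord_knee(seq_along(counts), counts)
  if (!is.na(k)) {
    return(structure(as.integer(counts[k]), degenerate = FALSE,
                     knee_index = k))
  }
  # The distinct spectrum is linear. That happens either because the
  # table is genuinely featureless (e.g. an arithmetic count sequence,
  # one gene per value) or because stray genes occupy every integer
  # count, hiding the density structure. The per-gene curve separates
  # the two: if it is linear too, flag degenerate and return the
  # minimum; otherwise find the knee on the per-gene curve with a
  # log-scaled index axis, which keeps the cut insensitive to the sheer
  # length of the singleton tail.
  cs <- sort(ft$count, decreasing = TRUE)
  if (length(unique(diff(cs))) == 1L) {
    return(structure(as.integer(min(counts)), degenerate = TRUE,
                     knee_index = NA_integer_))
  }
  xs <- log(seq_along(cs))
  j <- chord_knee(xs / max(xs), cs)
  if (is.na(j)) {
    return(structure(as.integer(min(counts)), degenerate = TRUE,
                     knee_index = NA_integer_))
  }
  structure(as.integer(cs[j]), degenerate = FALSE, knee_index = NA_integer_)
}

# Index of the point with maximum perpendicular distance to the chord
# joining the curve's endpoints (axes normalised to the unit square);
# NA when the curve is linear.
chord_knee <- function(xs, ys) {
  xs <- (xs - xs[1L]) / (xs[length(xs)] - xs[1L])
  span <- diff(range(ys))
  if (span <= 1e-12 * max(abs(ys), 1)) return(NA_integer_)
  ys <- (ys - min(ys)) / span
  dy <- ys[length(ys)] - ys[1L]
  dist <- abs(dy * (xs - xs[1L]) - (ys - ys[1L])) / sqrt(1 + dy^2)
  if (max(dist) < 1e-9) return(NA_integer_)
  which.max(dist)
}

#' Assemble the core signature from a frequency table
#'
#' Genes present in at least `threshold` selected archetypes, ordered by
#' decreasing count then lexically.
#'
#' @param ft a [gene_frequency()] table.
#' @param threshold integer count cut (use [knee_threshold()] to derive
#'   one).
#' @return a `metasig_signature` (character vector with `stage` and
#'   `provenance` attributes).
#' @export
core_signature <- function(ft, threshold) {
  genes <- ft$gene[ft$count >= threshold]
  if (length(genes) == 0L) {
    stop("no gene reaches the threshold (", threshold,
         "); consider lowering it")
  }
  new_signature(genes, stage = "core",
                provenance = list(threshold = as.integer(threshold),
                                  n_archetypes = attr(ft, "n_archetypes")))
}

new_signature <- function(genes, stage, provenance = list()) {
  structure(as.character(genes), class = "metasig_signature",
            stage = stage, provenance = provenance)
}

#' @export
print.metasig_signature <- function(x, ...) {
  cat("<metasig_signature> stage = ", attr(x, "stage"), ", ",
      length(x), " genes\n", sep = "")
  cat("  ", paste(head(unclass(x), 8L), collapse = ", "),
      if (length(x) > 8L) ", ...", "\n", sep = "")
  invisible(x)
}

#' Cell-type specificity of genes
#'
#' Per tumour (patient), a gene's specificity for a cell type is its mean
#' log-normalised expression in that type divided by the sum over types
#' (uniform when the gene is silent everywhere). Specificities are
#' averaged across tumours, re-normalised per gene, and the genes grouped
#' by Ward-linkage hierarchical clustering on Euclidean distances.
#'
#' @param mats a `lognorm_matrix` or list of them; `cell_meta` must carry
#'   `cell_type` and (for multiple tumours within one matrix) `patient_id`.
#' @param genes gene ids to profile (e.g. a core signature).
#' @param k_clusters number of gene clusters (default 9).
#' @return object of class `specificity_matrix`: `specificity` (genes x
#'   cell types, rows summing to 1), `clusters` (named integer vector).
#' @export
specificity_matrix <- function(mats, genes, k_clusters = 9) {
  if (k_clusters < 2) stop("k_clusters must be >= 2")
  if (inherits(mats, "lognorm_matrix")) mats <- list(mats)
  genes <- as.character(genes)
  per_tumour <- list()
  for (m in mats) {
    meta <- m$cell_meta
    if (is.null(meta$cell_type)) stop("cell_meta lacks cell_type")
    tumours <- if (!is.null(meta$patient_id)) meta$patient_id else "tumour1"
    X <- as.matrix(m$values[rownames(m$values) %in% genes, , drop = FALSE])
    for (tu in unique(tumours)) {
      cells <- tumours == tu
      Xt <- X[, cells, drop = FALSE]
      types <- meta$cell_type[cells]
      if (length(unique(types)) < 2L) next
      mm <- vapply(sort(unique(types)), function(ct) {
        rowMeans(Xt[, types == ct, drop = FALSE])
      }, numeric(nrow(X)))
      per_tumour[[length(per_tumour) + 1L]] <- normalise_rows(mm)
    }
  }
  if (length(per_tumour) == 0L) stop("need >= 2 cell types in some tumour")
  all_types <- sort(unique(unlist(lapply(per_tumour, colnames))))
  all_genes <- unique(unlist(lapply(per_tumour, rownames)))
  acc <- matrix(0, nrow = length(all_genes), ncol = length(all_types),
                dimnames = list(all_genes, all_types))
  cnt <- acc
  for (s in per_tumour) {
    g <- rownames(s)
    acc[g, colnames(s)] <- acc[g, colnames(s)] + s
    cnt[g, colnames(s)] <- cnt[g, colnames(s)] + 1
  }
  S <- acc / pmax(cnt, 1)
  S <- normalise_rows(S)
  missing <- setdiff(genes, rownames(S))
  if (length(missing)) {
    warning(length(missing), " signature gene(s) absent from the matrices")
  }
  kk <- min(k_clusters, nrow(S) - 1L)
  if (kk < k_clusters) {
    warning("fewer genes than requested clusters; using k = ", kk)
  }
  hc <- hclust(dist(S), method = "ward.D2")
  clusters <- cutree(hc, k = kk)
  structure(list(specificity = S, clusters = clusters, k_clusters = kk),
            class = "specificity_matrix")
}

normalise_rows <- function(M) {
  rs <- rowSums(M)
  out <- M / ifelse(rs > 0, rs, 1)
  out[rs == 0, ] <- 1 / ncol(M)
  out
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("<specificity_matrix> ", nrow(x$specificity), " genes x ",
      ncol(x$specificity), " cell types, ", x$k_clusters, " clusters\n",
      sep = "")
  invisible(x)
}

#' Refine a core signature by cell-type specificity
#'
#' Splits the core signature at the gene-cluster level: clusters whose
#' mean specificity for the target cell type exceeds every other type's
#' mean (and an optional floor) contribute the refined signature; the
#' remainder is the residual. Cluster indices are arbitrary, so selection
#' is by specificity profile rather than label.
#'
#' @param core a core `metasig_signature`.
#' @param sm a [specificity_matrix()] over (at least) the core genes.
#' @param target target cell type (default "epithelial").
#' @param min_mean_specificity optional floor on the selected clusters'
#'   mean target specificity.
#' @return list with elements `refined` and `residual` (both
#'   `metasig_signature`s) and `selected_clusters`.
#' @export
refine_signature <- function(core, sm, target = "epithelial",
                             min_mean_specificity = 0) {
  S <- sm$specificity
  if (!target %in% colnames(S)) {
    stop("target cell type '", target, "' absent from the specificity matrix")
  }
  cl <- sm$clusters
  ids <- sort(unique(cl))
  means <- t(vapply(ids, function(k) {
    colMeans(S[names(cl)[cl == k], , drop = FALSE])
  }, numeric(ncol(S))))
  rownames(means) <- ids
  others <- setdiff(colnames(S), target)
  picked <- ids[means[, target] > apply(means[, others, drop = FALSE], 1L, max) &
                  means[, target] >= min_mean_specificity]
  if (length(picked) == 0L) {
    stop("no cluster is specific to '", target, "'; per-cluster mean ",
         target, " specificity: ",
         paste(sprintf("%s=%.3f", ids, means[, target]), collapse = ", "))
  }
  ref_genes <- names(cl)[cl %in% picked]
  refined <- core[core %in% ref_genes]
  residual <- core[!core %in% ref_genes]
  prov <- list(parent = "core", target = target,
               clusters = as.integer(picked))
  list(refined = new_signature(refined, "refined", prov),
       residual = new_signature(residual, "residual", prov),
       selected_clusters = as.integer(picked),
       cluster_means = means)
}

#' Derive a metastatic signature from a multi-patient cohort
#'
#' End-to-end derivation. Per patient the counts are QC-filtered,
#' log-normalised and reduced to `d` principal components; the cells are
#' then decomposed into archetypes at every resolution in `resolutions`
#' (a multiresolution sweep up to `k_max`, mirroring how archetypal
#' expression programs are collected at several granularities), each
#' archetype's gene program is extracted and scored against the seed gene
#' sets, and the top `top_quantile` archetypes of every (patient,
#' resolution) fit are selected. Gene frequencies across all selected
#' archetype programs are counted and the core signature cut at the knee
#' of the count spectrum (or at an explicit `threshold`). When cell types
#' are annotated the core is refined to the target type via
#' [specificity_matrix()] and [refine_signature()].
#'
#' With `resolutions = "elbow"` a single resolution per patient is used
#' instead, chosen by [select_k()].
#'
#' @param matrices list of [sc_counts], one per patient.
#' @param seeds list of seed [gene_set]s.
#' @param qc apply [qc_filter()] first.
#' @param resolutions integer vector of archetype numbers to pool, or
#'   "elbow"; NULL defaults to `seq(max(2, k_max - 4), k_max, by = 2)`.
#' @param d,k_max,top_m,top_quantile,threshold,k_clusters,target
#'   stage parameters; see the stage functions.
#' @param r_max rank cap for scoring archetype programs; NULL aligns it
#'   with `top_m`, so an archetype is judged by the seed genes inside its
#'   program rather than by their ranks across the whole transcriptome.
#' @param min_genes_per_cell,min_cells_per_gene,max_mito_frac QC thresholds.
#' @param refine derive the refined/residual split (needs `cell_type`
#'   metadata).
#' @param fit_iter iteration budget per archetype fit in the sweep.
#' @param seed RNG seed for archetype initialisation.
#' @return object of class `metasig_derivation` with the core (and
#'   optionally refined/residual) signatures, the frequency table, the
#'   per-archetype score table, and per-patient fit summaries.
#' @export
derive_signature <- function(matrices, seeds, qc = TRUE, d = 20, k_max = 10,
                             resolutions = NULL, top_m = 200,
                             top_quantile = 0.25, r_max = NULL,
                             threshold = NULL, refine = TRUE,
                             target = "epithelial", k_clusters = 9,
                             min_genes_per_cell = 200, min_cells_per_gene = 3,
                             max_mito_frac = 0.20, fit_iter = 60, seed = 1L) {
  if (inherits(matrices, "sc_counts")) matrices <- list(matrices)
  if (is.null(names(matrices))) {
    names(matrices) <- vapply(seq_along(matrices), function(i) {
      pid <- unique(matrices[[i]]$cell_meta$patient_id)
      if (length(pid) == 1L && !is.null(pid)) as.character(pid)
      else sprintf("patient%02d", i)
    }, character(1))
  }
  if (is.null(r_max)) r_max <- top_m
  elbow <- identical(resolutions, "elbow")
  if (is.null(resolutions)) {
    resolutions <- seq(max(2, k_max - 4), k_max, by = 2)
  }
  lognorms <- list()
  fits <- list()
  member_lists <- list()
  score_rows <- list()
  for (p in names(matrices)) {
    x <- matrices[[p]]
    if (qc) {
      x <- qc_filter(x, min_genes_per_cell = min_genes_per_cell,
                     min_cells_per_gene = min_cells_per_gene,
                     max_mito_frac = max_mito_frac)
    }
    ln <- lognorm(x)
    emb <- reduce_pca(ln, d = d)
    res_p <- if (elbow) {
      as.integer(select_k(emb, k_max = k_max, seed = seed))
    } else resolutions
    for (k in res_p) {
      fit <- fit_archetypes(emb, k = k, max_iter = fit_iter, seed = seed)
      pr <- program_genes(fit, ln, top_m = top_m)
      sc <- score_programs(stats::setNames(list(pr), p), seeds,
                           r_max = r_max)
      sc <- select_archetypes(sc, top_quantile = top_quantile)
      sc$resolution <- k
      score_rows[[length(score_rows) + 1L]] <- sc
      sel_a <- sc$archetype[sc$selected]
      member_lists <- c(member_lists, pr$members[sel_a])
      fits[[paste(p, k, sep = ".k")]] <- fit
    }
    lognorms[[p]] <- ln
  }
  scores <- do.call(rbind, score_rows)
  ft <- gene_frequency(member_lists)
  thr <- knee_threshold(ft, override = threshold)
  core <- core_signature(ft, thr)
  out <- list(core = core, frequency = ft, threshold = thr,
              scores = scores, fits = fits,
              params = list(d = d, k_max = k_max,
                            resolutions = if (elbow) "elbow" else resolutions,
                            top_m = top_m, top_quantile = top_quantile,
                            r_max = r_max))
  if (refine) {
    sm <- specificity_matrix(lognorms, unclass(core),
                             k_clusters = k_clusters)
    spl <- refine_signature(core, sm, target = target)
    out$refined <- spl$refined
    out$residual <- spl$residual
    out$specificity <- sm
  }
  structure(out, class = "metasig_derivation")
}

#' @export
print.metasig_derivation <- function(x, ...) {
  cat("<metasig_derivation>\n")
  cat("  core signature:    ", length(x$core), " genes (threshold ",
      as.integer(x$threshold), ")\n", sep = "")
  if (!is.null(x$refined)) {
    cat("  refined / residual: ", length(x$refined), " / ",
        length(x$residual), " genes\n", sep = "")
  }
  cat("  patients:          ", length(unique(x$scores$patient)), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.metasig_derivation <- function(object, ...) {
  print(object)
  cat("  resolutions:            ",
      paste(object$params$resolutions, collapse = ", "), "\n")
  sel <- object$scores[object$scores$selected, ]
  cat("  selected archetypes:    ", nrow(sel), " of ",
      nrow(object$scores), "\n", sep = "")
  invisible(object)
}

#' Packaged reference signature lists
#'
#' Returns the packaged 177-gene (refined, epithelial-specific), 109-gene
#' (residual, microenvironment) or 286-gene (core union) signature list.
#' These fixtures are synthetic stand-ins (placeholder symbols
#' MSG0001..MSG0286) that mirror the published split sizes; they are not
#' the published gene identities.
#'
#' @param stage one of "refined", "residual", "core".
#' @return a `metasig_signature`.
#' @export
packaged_signature <- function(stage = c("refined", "residual", "core")) {
  stage <- match.arg(stage)
  f <- function(name) {
    read_gene_list(system.file("extdata", name, package = "metasig",
                               mustWork = TRUE))
  }
  refined <- f("signature_refined_177_synthetic.txt")
  residual <- f("signature_residual_109_synthetic.txt")
  genes <- switch(stage, refined = refined, residual = residual,
                  core = c(refined, residual))
  new_signature(genes, stage = stage,
                provenance = list(source = "packaged synthetic fixture"))
}
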