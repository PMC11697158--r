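#' Construct a gene set
#'
#' @param name label for the set.
#' @param genes character vector of unique gene ids (non-empty).
#' @param tier provenance tier: "single-evidence", "multi-evidence" or
#'   "derived".
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes,
                     tier = c("derived", "single-evidence", "multi-evidence")) {
  tier <- match.arg(tier)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    stop("gene set '", name, "' contains duplicates")
  }
  structure(list(name = name, genes = genes, tier = tier),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, " (", x$tier, "): ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}

#' Capped relative expression ranks within one unit
#'
#' Ranks a unit's per-gene expression in decreasing order; ties receive the
#' mean of their rank range; any rank exceeding `r_max` is replaced by
#' `r_max + 1` so that genes outside the top of the transcriptome
#' contribute a constant, composition-independent penalty.
#'
#' @param values numeric vector of per-gene expression for one unit.
#' @param r_max rank cap (>= 1).
#' @return numeric vector of capped ranks.
#' @export
relative_ranks <- function(values, r_max) {
  if (r_max < 1) stop("r_max must be >= 1")
  if (any(!is.finite(values))) stop("non-finite expression values")
  r <- rank(-values, ties.method = "average")
  r[r > r_max] <- r_max + 1
  r
}

#' Rank-based (Mann-Whitney U) gene-set score
#'
#' Per-unit gene-set activity on the U-statistic scale. For unit u with
#' capped ranks r(g, u),
#' \deqn{U'(u) = \sum_{g \in s} r(g,u) - n_g(n_g+1)/2,\qquad
#'   score(u) = \max(0,\ 1 - U'(u)/(n_g\, r_{max}))}
#' where n_g is the number of signature genes present in the matrix. The
#' score lies in [0, 1], depends only on within-unit ranks (so any
#' monotone transform of expression gives the same result) and is
#' unaffected by which other units are present.
#'
#' @param m genes x units matrix: a `lognorm_matrix`, an `sc_counts`, or a
#'   plain numeric matrix with gene rownames (e.g. archetype footprints).
#' @param s a [gene_set] or character vector of gene ids.
#' @param r_max rank cap; the conventional default is 1500.
#' @return named numeric vector of scores with attributes `r_max` and
#'   `n_genes_used`.
#' @export
set_score <- function(m, s, r_max = 1500) {
  genes <- if (inherits(s, "gene_set")) s$genes else as.character(s)
  vals <- as_dense_values(m)
  if (nrow(vals) < 2L) stop("units must have at least 2 genes")
  present <- genes[genes %in% rownames(vals)]
  if (length(present) == 0L) {
    stop("no signature genes found in the matrix; missing: ",
         paste(head(genes, 10L), collapse = ", "))
  }
  sig_idx <- match(present, rownames(vals))
  n_g <- length(present)
  scores <- vapply(seq_len(ncol(vals)), function(j) {
    r <- relative_ranks(vals[, j], r_max)
    u <- sum(r[sig_idx]) - n_g * (n_g + 1) / 2
    max(0, 1 - u / (n_g * r_max))
  }, numeric(1))
  names(scores) <- colnames(vals)
  attr(scores, "r_max") <- r_max
  attr(scores, "n_genes_used") <- n_g
  scores
}
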