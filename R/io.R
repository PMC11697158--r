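#' Single-cell count matrix with cell metadata
#'
#' Container for a genes x cells matrix of UMI counts plus per-cell
#' metadata. Counts must be non-negative integers; gene ids must be unique.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) with
#'   dimnames giving gene ids and cell ids.
#' @param cell_meta data.frame with one row per cell. Must contain
#'   `cell_id`; `patient_id`, `sample_id`, `cancer_type` and `cell_type`
#'   are carried along when present. If NULL a minimal frame is built.
#' @return an object of class `sc_counts` (list with `counts`, `cell_meta`).
#' @export
sc_counts <- function(counts, cell_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids (rownames) and cell ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicate gene id: ", dup)
  }
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  vals <- counts@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    bad <- which(vals < 0 | vals != round(vals))[1L]
    stop("counts must be non-negative integers (offending value ",
         vals[bad], ")")
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts),
                            stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta)) stop("cell_meta needs a cell_id column")
  if (!identical(as.character(cell_meta$cell_id), colnames(counts))) {
    cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), ,
                           drop = FALSE]
    if (anyNA(cell_meta$cell_id)) {
      stop("cell_meta does not cover all cells in counts")
    }
    rownames(cell_meta) <- NULL
  }
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat("<sc_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  if (!is.null(x$cell_meta$patient_id)) {
    cat("  patients: ", paste(unique(x$cell_meta$patient_id),
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Supports the MatrixMarket triplet layout (a directory holding
#' `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and optionally `cells.tsv`
#' with cell metadata) and a dense TSV (genes in rows, first column the
#' gene id).
#'
#' @param path directory (mtx) or file (dense_tsv).
#' @param format one of "mtx", "dense_tsv".
#' @return an [sc_counts] object. Integer data round-trips bit-exactly
#'   through [write_counts()].
#' @export
read_counts <- function(path, format = c("mtx", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx_file <- file.path(path, "matrix.mtx")
    genes_file <- file.path(path, "genes.tsv")
    bc_file <- file.path(path, "barcodes.tsv")
    for (f in c(mtx_file, genes_file, bc_file)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    m <- Matrix::readMM(mtx_file)
    genes <- read.table(genes_file, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    barcodes <- read.table(bc_file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(genes)) {
      stop("format error: matrix declares ", nrow(m),
           " genes but genes.tsv lists ", length(genes))
    }
    if (ncol(m) != length(barcodes)) {
      stop("format error: matrix declares ", ncol(m),
           " cells but barcodes.tsv lists ", length(barcodes))
    }
    dimnames(m) <- list(genes, barcodes)
    meta_file <- file.path(path, "cells.tsv")
    meta <- if (file.exists(meta_file)) {
      read.table(meta_file, sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
    } else NULL
    sc_counts(m, meta)
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    genes <- tab[[1L]]
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- genes
    storage.mode(m) <- "double"
    sc_counts(m)
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; the mtx layout writes `matrix.mtx`,
#' `genes.tsv`, `barcodes.tsv` and `cells.tsv`.
#'
#' @param x an [sc_counts] object.
#' @param path output directory (mtx) or file (dense_tsv).
#' @param format one of "mtx", "dense_tsv".
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "dense_tsv")) {
  stopifnot(inherits(x, "sc_counts"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
    writeLines(rownames(x$counts), file.path(path, "genes.tsv"))
    writeLines(colnames(x$counts), file.path(path, "barcodes.tsv"))
    write.table(x$cell_meta, file.path(path, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene = rownames(x$counts),
                      as.matrix(x$counts), check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments are skipped;
#' duplicates are dropped keeping first occurrence.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Write a plain-text gene list
#'
#' One symbol per line, readable back with [read_gene_list()].
#'
#' @param genes character vector (or `metasig_signature`/[gene_set]).
#' @param path file path.
#' @param header optional comment line written with a `#` prefix.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path, header = NULL) {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  lines <- as.character(genes)
  if (!is.null(header)) lines <- c(paste("#", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Materialises a [simulate_cohort()] result in the standard exchange
#' layout: one MatrixMarket triplet directory per patient (see
#' [write_counts()]), the two seed gene lists as plain text, and the
#' ground truth as JSON.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing the ground-truth JSON requires the jsonlite package")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(sim$matrices)) {
    write_counts(sim$matrices[[p]], file.path(dir, p), format = "mtx")
  }
  for (s in sim$seed_sets) {
    write_gene_list(s, file.path(dir, paste0("seeds_", s$name, ".txt")),
                    header = paste("tier:", s$tier))
  }
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Quality-control filtering of cells and genes
#'
#' Retains cells with more than `min_genes_per_cell` detected genes
#' (detection = count > 0) and a mitochondrial count fraction of at most
#' `max_mito_frac`, and genes detected in at least `min_cells_per_gene`
#' cells. The two filters are re-applied until a joint fixed point so the
#' result is idempotent and both conditions hold on the returned matrix.
#'
#' @param x an [sc_counts] object.
#' @param min_genes_per_cell strict lower bound on detected genes per cell.
#' @param min_cells_per_gene minimum cells a gene must be detected in.
#' @param max_mito_frac maximum mitochondrial count fraction per cell.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @return filtered [sc_counts]; the removal tally is attached as
#'   attribute `qc_report`.
#' @export
qc_filter <- function(x, min_genes_per_cell = 200, min_cells_per_gene = 3,
                      max_mito_frac = 0.20, mito_prefix = "MT-") {
  stopifnot(inherits(x, "sc_counts"))
  m <- x$counts
  n_cells0 <- ncol(m)
  n_genes0 <- nrow(m)
  repeat {
    mito <- startsWith(rownames(m), mito_prefix)
    tot <- Matrix::colSums(m)
    detected <- Matrix::colSums(m > 0)
    mito_frac <- if (any(mito)) {
      ifelse(tot > 0, Matrix::colSums(m[mito, , drop = FALSE]) / tot, 0)
    } else rep(0, ncol(m))
    keep_cells <- detected > min_genes_per_cell & mito_frac <= max_mito_frac
    if (!any(keep_cells)) {
      stop("qc_filter removed all cells (thresholds: >",
           min_genes_per_cell, " genes, mito <= ", max_mito_frac, ")")
    }
    m2 <- m[, keep_cells, drop = FALSE]
    keep_genes <- Matrix::rowSums(m2 > 0) >= min_cells_per_gene
    m2 <- m2[keep_genes, , drop = FALSE]
    if (nrow(m2) == 0L) stop("qc_filter removed all genes")
    stable <- all(keep_cells) && all(keep_genes)
    m <- m2
    if (stable) break
  }
  meta <- x$cell_meta[match(colnames(m), x$cell_meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  out <- structure(list(counts = m, cell_meta = meta), class = "sc_counts")
  attr(out, "qc_report") <- list(
    cells_in = n_cells0, cells_kept = ncol(m),
    genes_in = n_genes0, genes_kept = nrow(m),
    min_genes_per_cell = min_genes_per_cell,
    min_cells_per_gene = min_cells_per_gene,
    max_mito_frac = max_mito_frac)
  out
}

#' Library-size normalisation with log transform
#'
#' Scales each cell's counts to a common total (`scale_factor`) and applies
#' `log(1 + x)`. Zero counts map to zero, so sparsity is preserved; values
#' depend only on within-cell proportions, making them invariant to
#' sequencing depth.
#'
#' @param x an [sc_counts] object with no zero-total cells (run
#'   [qc_filter()] first).
#' @param scale_factor library-size scale (default 10,000).
#' @return an object of class `lognorm_matrix` (list with sparse `values`
#'   genes x cells and `cell_meta`).
#' @export
lognorm <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "sc_counts"))
  m <- x$counts
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) {
    stop("zero-total cell(s): ",
         paste(head(colnames(m)[tot == 0], 5L), collapse = ", "))
  }
  v <- m
  v@x <- log1p(scale_factor * v@x / rep.int(tot, diff(v@p)))
  structure(list(values = v, cell_meta = x$cell_meta),
            class = "lognorm_matrix")
}

#' @export
print.lognorm_matrix <- function(x, ...) {
  cat("<lognorm_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells\n", sep = "")
  invisible(x)
}

#' @export
dim.lognorm_matrix <- function(x) dim(x$values)
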