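#' Reduce a cell population to a low-dimensional embedding
#'
#' Principal-component reduction of gene-standardised log expression:
#' each gene is centred and scaled to unit variance across cells
#' (zero-variance genes dropped), then the top `d` components are taken.
#' A randomised truncated SVD keeps the reduction fast on large matrices;
#' it is deterministic for identical input.
#'
#' @param m a `lognorm_matrix` (or genes x cells matrix).
#' @param d number of components (default 20).
#' @return object of class `reduced_embedding`: `coordinates` (cells x d
#'   scores), `explained_variance` (non-increasing), `rotation` (genes x d)
#'   and `genes_used`.
#' @export
reduce_pca <- function(m, d = 20) {
  X <- as_dense_values(m)                    # genes x cells
  n <- ncol(X)
  if (n <= d) stop("need more cells (", n, ") than dimensions (", d, ")")
  sds <- apply(X, 1L, sd)
  keep <- sds > 0
  if (!any(keep)) stop("degenerate input: all genes constant across cells")
  Xs <- (X[keep, , drop = FALSE] - rowMeans(X[keep, , drop = FALSE])) /
    sds[keep]
  M <- t(Xs)                                 # cells x genes, column-centred
  sv <- rand_svd(M, d = min(d, min(dim(M))))
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(coords) <- colnames(X)
  ev <- sv$d^2 / (n - 1)
  structure(list(coordinates = coords,
                 explained_variance = ev,
                 rotation = sv$v,
                 genes_used = rownames(X)[keep],
                 cell_meta = get_cell_meta(m)),
            class = "reduced_embedding")
}

#' @export
print.reduced_embedding <- function(x, ...) {
  cat("<reduced_embedding> ", nrow(x$coordinates), " cells x ",
      ncol(x$coordinates), " components\n", sep = "")
  invisible(x)
}

# Furthest-point (maximin) initialisation: start from the point farthest
# from the centroid (an extreme by construction), then greedily add the
# point maximising the minimum distance to those already chosen. Unlike a
# summed-distance rule this cannot pick a duplicate of an already-chosen
# extreme over an unexplored cluster.
furthest_point_init <- function(X, k) {
  n <- ncol(X)
  ctr <- rowMeans(X)
  idx <- which.max(colSums((X - ctr)^2))
  mind <- rep(Inf, n)
  while (length(idx) < k) {
    last <- idx[length(idx)]
    mind <- pmin(mind, sqrt(colSums((X - X[, last])^2)))
    avail <- setdiff(seq_len(n), idx)
    idx <- c(idx, avail[which.max(mind[avail])])
  }
  idx
}

# One projected-gradient descent pass with backtracking on a column-simplex
# constrained factor. f must only decrease; returns the updated factor,
# objective and step size.
pg_step <- function(P, grad, obj_fun, f0, step) {
  for (try in 1:25) {
    Pn <- proj_simplex_cols(P - step * grad)
    fn <- obj_fun(Pn)
    if (fn <= f0) return(list(P = Pn, f = fn, step = step * 1.3))
    step <- step / 2
  }
  list(P = P, f = f0, step = step)
}

#' Fit an archetypal (principal convex hull) decomposition
#'
#' Models every cell as a convex combination of k archetypes, each
#' archetype itself a convex combination of cells:
#' minimise ||X - X B A||_F^2 with column-stochastic B (n x k) and
#' A (k x n). Optimisation alternates projected-gradient updates of A and
#' B with backtracking line search from a furthest-point (maximin) initialisation, so
#' the residual sum of squares never increases. Archetypes claiming fewer
#' than `min_cells_per_arch` cells (by argmax loading, ties to the lowest
#' archetype index) are dropped and the loadings refit.
#'
#' @param e a [reduce_pca()] embedding.
#' @param k number of archetypes (2 <= k <= n_cells).
#' @param max_iter maximum alternating iterations.
#' @param tol relative RSS change declaring convergence.
#' @param seed RNG seed for the initialisation.
#' @param min_cells_per_arch minimum cells an archetype must claim.
#' @return object of class `archetype_fit` with `archetype_coords` (k x d),
#'   `cell_loadings` (cells x k, rows on the simplex), `archetype_weights`
#'   (cells x k defining archetypes as convex combinations of cells),
#'   `rss`, `rss_trace`, `cells_per_archetype`, `converged`, `k`.
#' @export
fit_archetypes <- function(e, k, max_iter = 250, tol = 1e-7, seed = 1L,
                           min_cells_per_arch = 5L) {
  stopifnot(inherits(e, "reduced_embedding"))
  X <- t(e$coordinates)                      # d x n
  n <- ncol(X)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  if (k < 2L) stop("k must be at least 2")

  init <- with_seed(seed, furthest_point_init(X, k))
  B <- matrix(0, n, k)
  B[cbind(init, seq_len(k))] <- 1
  A <- matrix(1 / k, k, n)

  obj_A <- function(A, Z) sum((X - Z %*% A)^2)
  f <- obj_A(A, X %*% B)
  sA <- 1; sB <- 1
  trace <- f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f_prev <- f
    Z <- X %*% B
    for (sub in 1:4) {
      G <- 2 * crossprod(Z, Z %*% A - X)
      st <- pg_step(A, G, function(P) obj_A(P, Z), f, sA)
      A <- st$P; f <- st$f; sA <- st$step
    }
    for (sub in 1:2) {
      R <- (X %*% B) %*% A - X
      GB <- 2 * crossprod(X, R %*% t(A))
      st <- pg_step(B, GB, function(P) obj_A(A, X %*% P), f, sB)
      B <- st$P; f <- st$f; sB <- st$step
    }
    trace <- c(trace, f)
    if (f_prev - f < tol * max(f_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }

  # drop under-populated archetypes and refit loadings
  repeat {
    assign <- max.col(t(A), ties.method = "first")
    counts <- tabulate(assign, nbins = ncol(B))
    if (ncol(B) <= 2L || all(counts >= min_cells_per_arch)) break
    drop_j <- which.min(counts)
    B <- B[, -drop_j, drop = FALSE]
    A <- A[-drop_j, , drop = FALSE]
    cs <- colSums(A)
    A <- sweep(A, 2L, ifelse(cs > 0, cs, 1), "/")
    A[, cs == 0] <- 1 / nrow(A)
    Z <- X %*% B
    f <- obj_A(A, Z)
    for (it in seq_len(50L)) {
      G <- 2 * crossprod(Z, Z %*% A - X)
      st <- pg_step(A, G, function(P) obj_A(P, Z), f, sA)
      if (f - st$f < tol * max(f, .Machine$double.eps)) { A <- st$P; f <- st$f; break }
      A <- st$P; f <- st$f; sA <- st$step
    }
    trace <- c(trace, f)
  }

  k_final <- ncol(B)
  Z <- t(X %*% B)                            # k x d archetype coordinates
  assign <- max.col(t(A), ties.method = "first")
  structure(list(k = k_final,
                 archetype_coords = Z,
                 cell_loadings = t(A),
                 archetype_weights = B,
                 rss = f,
                 rss_trace = trace,
                 cells_per_archetype = tabulate(assign, nbins = k_final),
                 converged = converged,
                 k_requested = k),
            class = "archetype_fit")
}

#' @export
print.archetype_fit <- function(x, ...) {
  cat("<archetype_fit> k = ", x$k,
      if (x$k != x$k_requested) paste0(" (requested ", x$k_requested, ")"),
      ", RSS = ", signif(x$rss, 5),
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' @export
summary.archetype_fit <- function(object, ...) {
  cat("Archetypal decomposition\n")
  cat("  archetypes:          ", object$k, "\n")
  cat("  cells:               ", nrow(object$cell_loadings), "\n")
  cat("  residual SS:         ", signif(object$rss, 6), "\n")
  cat("  cells per archetype: ",
      paste(object$cells_per_archetype, collapse = ", "), "\n")
  invisible(object)
}

#' Choose the number of archetypes by the RSS elbow
#'
#' Fits k = 2..k_max and returns the elbow of the RSS-vs-k curve: the k
#' with maximum perpendicular distance to the chord joining the curve's
#' endpoints (axes normalised to the unit square). A near-linear curve is
#' flagged degenerate and yields k = 2.
#'
#' @param e a [reduce_pca()] embedding.
#' @param k_max largest k to consider (default 10).
#' @param seed,min_cells_per_arch,max_iter passed to [fit_archetypes()].
#' @param subsample cap on the number of cells used for the scan (the
#'   RSS-vs-k shape is stable under subsampling and the scan dominates
#'   run time); NULL uses all cells.
#' @return integer k with attributes `rss` (named vector) and `degenerate`.
#' @export
select_k <- function(e, k_max = 10, seed = 1L, min_cells_per_arch = 5L,
                     max_iter = 60, subsample = 500L) {
  if (k_max < 2) stop("k_max must be >= 2")
  n <- nrow(e$coordinates)
  if (!is.null(subsample) && n > subsample) {
    idx <- with_seed(seed, sort(sample.int(n, subsample)))
    e <- structure(list(coordinates = e$coordinates[idx, , drop = FALSE],
                        explained_variance = e$explained_variance),
                   class = "reduced_embedding")
  }
  ks <- 2:k_max
  rss <- vapply(ks, function(k) {
    fit_archetypes(e, k, max_iter = max_iter, seed = seed,
                   min_cells_per_arch = min_cells_per_arch)$rss
  }, numeric(1))
  names(rss) <- ks
  pick <- elbow_pick(ks, rss)
  structure(pick$k, rss = rss, degenerate = pick$degenerate)
}

# Elbow of a decreasing curve: the k at maximum perpendicular distance to
# the chord joining the endpoints (unit-square normalised axes). An
# exactly linear curve is degenerate and yields the smallest k.
elbow_pick <- function(ks, rss) {
  xs <- (ks - min(ks)) / max(1, diff(range(ks)))
  span <- diff(range(rss))
  if (span <= 1e-12 * max(abs(rss), 1)) {
    return(list(k = as.integer(min(ks)), degenerate = TRUE))
  }
  ys <- (rss - min(rss)) / span
  dx <- xs[length(xs)] - xs[1L]; dy <- ys[length(ys)] - ys[1L]
  dist <- abs(dy * (xs - xs[1L]) - dx * (ys - ys[1L])) / sqrt(dx^2 + dy^2)
  if (max(dist) < 1e-9) {
    return(list(k = as.integer(min(ks)), degenerate = TRUE))
  }
  list(k = as.integer(ks[which.max(dist)]), degenerate = FALSE)
}

#' Archetype gene programs (footprints)
#'
#' For each archetype a and gene g, the footprint is the loading-weighted
#' mean log expression \eqn{\sum_c A_{ca} x_{gc} / \sum_c A_{ca}},
#' z-scored per gene across archetypes so that a program highlights the
#' genes distinguishing its archetype from the rest of the sample.
#' Member genes are the `top_m` genes by footprint.
#'
#' @param model an [fit_archetypes()] result.
#' @param m the `lognorm_matrix` the model was fitted on.
#' @param top_m program size (clamped to the gene universe with a warning).
#' @return object of class `archetype_programs`: `footprint` (genes x k
#'   z-score matrix), `members` (list of character vectors), `degenerate_z`
#'   flag (TRUE when archetypes are indistinguishable).
#' @export
program_genes <- function(model, m, top_m = 200) {
  stopifnot(inherits(model, "archetype_fit"))
  X <- as_dense_values(m)                    # genes x cells
  A <- model$cell_loadings                   # cells x k
  if (nrow(A) != ncol(X)) {
    stop("model was fitted on ", nrow(A), " cells but the matrix has ",
         ncol(X))
  }
  if (top_m > nrow(X)) {
    warning("top_m (", top_m, ") exceeds the number of genes (", nrow(X),
            "); clamping")
    top_m <- nrow(X)
  }
  W <- sweep(A, 2L, pmax(colSums(A), .Machine$double.eps), "/")
  F0 <- X %*% W                              # genes x k weighted means
  mu <- rowMeans(F0)
  sdv <- apply(F0, 1L, sd)
  degenerate <- all(sdv < 1e-12)
  Fz <- (F0 - mu) / ifelse(sdv > 1e-12, sdv, 1)
  Fz[sdv <= 1e-12, ] <- 0
  rownames(Fz) <- rownames(X)
  members <- lapply(seq_len(ncol(Fz)), function(j) {
    ord <- order(-Fz[, j], rownames(Fz))
    rownames(Fz)[ord][seq_len(top_m)]
  })
  structure(list(footprint = Fz, members = members,
                 degenerate_z = degenerate, top_m = top_m),
            class = "archetype_programs")
}

#' @export
print.archetype_programs <- function(x, ...) {
  cat("<archetype_programs> ", ncol(x$footprint), " archetypes, top_m = ",
      x$top_m, if (x$degenerate_z) " (degenerate z)", "\n", sep = "")
  invisible(x)
}
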