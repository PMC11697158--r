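# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state so seeded generators never perturb user randomness.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Column-wise Euclidean projection onto the probability simplex
# (Duchi et al. algorithm, vectorised over columns). M is k x n; every
# column of the result is non-negative and sums to 1.
proj_simplex_cols <- function(M) {
  k <- nrow(M)
  n <- ncol(M)
  if (k == 1L) return(matrix(1, 1L, n))
  o <- order(col(M), -M)               # sort each column descending
  Ms <- matrix(M[o], k, n)
  CS <- Ms
  for (i in 2:k) CS[i, ] <- CS[i - 1L, ] + Ms[i, ]
  idx <- seq_len(k)
  cond <- Ms > (CS - 1) / idx          # idx recycles down columns
  rho <- colSums(cond)                 # last index satisfying the condition
  theta <- (CS[cbind(rho, seq_len(n))] - 1) / rho
  P <- M - rep(theta, each = k)
  P[P < 0] <- 0
  P
}

# Randomised truncated SVD (Halko-style, q power iterations). A is n x m;
# returns the top-d triplet. The Gaussian test matrix is drawn under a
# fixed internal seed so results are deterministic for identical input.
rand_svd <- function(A, d, q = 2L, oversample = 10L, seed = 1L) {
  m <- ncol(A)
  l <- min(m, d + oversample)
  Omega <- with_seed(seed, matrix(stats::rnorm(m * l), m, l))
  Y <- A %*% Omega
  for (i in seq_len(q)) {
    Y <- qr.Q(qr(Y))
    Y <- A %*% crossprod(A, Y)
  }
  Q <- qr.Q(qr(Y))
  B <- crossprod(Q, A)                 # l x m
  s <- svd(B, nu = min(d, l), nv = min(d, l))
  d_keep <- seq_len(min(d, length(s$d)))
  list(u = (Q %*% s$u)[, d_keep, drop = FALSE],
       d = s$d[d_keep],
       v = s$v[, d_keep, drop = FALSE])
}

# Dense numeric matrix from a CountMatrix / LogNormMatrix / plain matrix.
as_dense_values <- function(x) {
  if (inherits(x, "lognorm_matrix")) return(as.matrix(x$values))
  if (inherits(x, "sc_counts")) return(as.matrix(x$counts))
  if (inherits(x, "Matrix")) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  stop("cannot interpret input as a genes x units matrix")
}

# Cell metadata from supported containers (or NULL).
get_cell_meta <- function(x) {
  if (inherits(x, c("lognorm_matrix", "sc_counts"))) x$cell_meta else NULL
}
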