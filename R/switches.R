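#' Binarise log expression into on/off states
#'
#' A gene is "on" in a cell when its log-normalised expression is at least
#' `cutoff` (the boundary value maps to on).
#'
#' @param m `lognorm_matrix` or genes x cells matrix of values >= 0.
#' @param cutoff on/off threshold (default 0.2).
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize <- function(m, cutoff = 0.2) {
  X <- as_dense_values(m)
  if (any(X < 0)) stop("expression values must be >= 0")
  out <- (X >= cutoff) * 1L
  dimnames(out) <- dimnames(X)
  out
}

#' Logistic switch-time fit for one gene
#'
#' Regresses the binary on/off state on pseudotime (logistic regression by
#' iteratively reweighted least squares). The switch time t* is the
#' pseudotime at which the fitted on-probability crosses 0.5
#' (t* = -beta0/beta1); the direction is "on" for positive slope, "off"
#' otherwise; fit quality is McFadden's pseudo-R^2,
#' 1 - loglik(model)/loglik(intercept-only). Complete separation
#' (vanishing residual deviance) is flagged and reported with
#' pseudo-R^2 = 1; genes stuck in one state are flagged degenerate and
#' not fitted. t* is reported only when it falls inside the observed
#' pseudotime range (otherwise flagged out of range).
#'
#' @param states 0/1 (or logical) vector over cells (>= 20 cells).
#' @param pseudotime numeric vector in [0, 1], not constant.
#' @return one-row data.frame: gene (NA; filled by [fit_switches()]),
#'   beta0, beta1, switch_time, direction, pseudo_r2, degenerate,
#'   separation, t_in_range.
#' @export
fit_switch <- function(states, pseudotime) {
  states <- as.numeric(states)
  if (length(states) < 20L) stop("need at least 20 cells")
  if (length(states) != length(pseudotime)) stop("length mismatch")
  if (diff(range(pseudotime)) == 0) stop("constant pseudotime")
  row <- data.frame(gene = NA_character_, beta0 = NA_real_,
                    beta1 = NA_real_, switch_time = NA_real_,
                    direction = NA_character_, pseudo_r2 = NA_real_,
                    degenerate = FALSE, separation = FALSE,
                    t_in_range = NA, stringsAsFactors = FALSE)
  if (length(unique(states)) < 2L) {
    row$degenerate <- TRUE
    return(row)
  }
  g <- suppressWarnings(
    glm(states ~ pseudotime, family = binomial(),
        control = glm.control(maxit = 100, epsilon = 1e-8)))
  b <- coef(g)
  row$beta0 <- b[[1L]]
  row$beta1 <- b[[2L]]
  row$pseudo_r2 <- max(0, min(1, 1 - g$deviance / g$null.deviance))
  if (g$deviance < 1e-6) {
    row$separation <- TRUE
    row$pseudo_r2 <- 1
  }
  if (is.finite(row$beta1) && row$beta1 != 0) {
    ts <- -row$beta0 / row$beta1
    row$t_in_range <- ts >= min(pseudotime) && ts <= max(pseudotime)
    if (row$t_in_range) row$switch_time <- ts
    row$direction <- if (row$beta1 > 0) "on" else "off"
  }
  row
}

#' Fit switch times for every gene of a binarised matrix
#'
#' @param states genes x cells 0/1 matrix (see [binarize()]).
#' @param pseudotime numeric vector over cells.
#' @return data.frame of class `switch_fits`, one row per gene.
#' @export
fit_switches <- function(states, pseudotime) {
  rows <- lapply(seq_len(nrow(states)), function(i) {
    r <- fit_switch(states[i, ], pseudotime)
    r$gene <- rownames(states)[i] %||% as.character(i)
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("switch_fits", "data.frame")
  out
}

#' Rank switch genes by fit confidence and order them on the timeline
#'
#' Keeps non-degenerate fits with an in-range switch time, ranks them by
#' pseudo-R^2 (ties by |beta1|), takes the `top_n` most confident, and
#' returns them ordered by switch time. The confidence rank is kept in
#' the `confidence_rank` column.
#'
#' @param fits a [fit_switches()] table.
#' @param top_n number of genes to keep (default 50).
#' @return data.frame of class `switch_fits`, top genes sorted by
#'   `switch_time`.
#' @export
rank_switches <- function(fits, top_n = 50) {
  ok <- !fits$degenerate & !is.na(fits$switch_time)
  if (!any(ok)) stop("no non-degenerate switch fit available")
  f <- fits[ok, , drop = FALSE]
  ord <- order(-f$pseudo_r2, -abs(f$beta1))
  f <- f[ord, , drop = FALSE]
  f$confidence_rank <- seq_len(nrow(f))
  f <- f[seq_len(min(top_n, nrow(f))), , drop = FALSE]
  f <- f[order(f$switch_time), , drop = FALSE]
  rownames(f) <- NULL
  class(f) <- c("switch_fits", "data.frame")
  f
}
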