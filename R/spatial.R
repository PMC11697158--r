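#' Spatial transcriptomics slide
#'
#' @param spots data.frame with `spot_id`, `x`, `y`, `region` (every spot
#'   labelled; coordinates finite).
#' @param counts genes x spots count matrix with dimnames matching
#'   `spots$spot_id`.
#' @return object of class `spatial_slide`.
#' @export
spatial_slide <- function(spots, counts) {
  need <- c("spot_id", "x", "y", "region")
  miss <- setdiff(need, names(spots))
  if (length(miss)) stop("spots lacks: ", paste(miss, collapse = ", "))
  if (any(!is.finite(spots$x)) || any(!is.finite(spots$y))) {
    stop("spot coordinates must be finite")
  }
  if (anyNA(spots$region) || any(!nzchar(spots$region))) {
    stop("every spot must carry a region label")
  }
  if (!identical(as.character(spots$spot_id), colnames(counts))) {
    counts <- counts[, match(spots$spot_id, colnames(counts)), drop = FALSE]
    if (anyNA(colnames(counts))) stop("counts do not cover all spots")
  }
  structure(list(spots = spots,
                 counts = Matrix::Matrix(counts, sparse = TRUE)),
            class = "spatial_slide")
}

#' @export
print.spatial_slide <- function(x, ...) {
  cat("<spatial_slide> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " spots; regions: ",
      paste(names(table(x$spots$region)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score spatial spots with a gene signature
#'
#' Log-normalises the spot counts and delegates to [set_score()]; each
#' spot's score depends only on its own within-spot expression ranks.
#'
#' @param slide a [spatial_slide].
#' @param signature `metasig_signature`, [gene_set] or character vector.
#' @param r_max rank cap for [set_score()].
#' @param scale_factor library-size scale for the normalisation.
#' @return named numeric score vector over spots.
#' @export
score_spots <- function(slide, signature, r_max = 1500, scale_factor = 1e4) {
  stopifnot(inherits(slide, "spatial_slide"))
  x <- sc_counts(slide$counts,
                 data.frame(cell_id = slide$spots$spot_id,
                            stringsAsFactors = FALSE))
  set_score(lognorm(x, scale_factor = scale_factor), signature,
            r_max = r_max)
}

#' Region enrichment test for spot scores
#'
#' One-sided Wilcoxon rank-sum test that the focal region's scores exceed
#' all other spots' (exact when the smaller group has at most 8 spots and
#' no ties; normal approximation with tie correction otherwise), plus
#' per-region medians for ordering regions.
#'
#' @param scores per-spot scores.
#' @param regions region label per spot.
#' @param focal_region region tested for enrichment.
#' @return object of class `region_test`: `statistic` (W), `p`,
#'   `median_diff` (focal minus rest), `region_medians`, `exact`.
#' @export
region_test <- function(scores, regions, focal_region) {
  stopifnot(length(scores) == length(regions))
  if (!focal_region %in% regions) stop("empty focal region: ", focal_region)
  focal <- scores[regions == focal_region]
  rest <- scores[regions != focal_region]
  if (length(rest) == 0L) stop("no spots outside the focal region")
  use_exact <- min(length(focal), length(rest)) <= 8 &&
    !anyDuplicated(c(focal, rest))
  wt <- suppressWarnings(
    wilcox.test(focal, rest, alternative = "greater", exact = use_exact,
                correct = !use_exact))
  medians <- tapply(scores, regions, median)
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 median_diff = median(focal) - median(rest),
                 region_medians = medians, focal_region = focal_region,
                 exact = use_exact),
            class = "region_test")
}

#' @export
print.region_test <- function(x, ...) {
  cat("<region_test> '", x$focal_region, "' vs rest: W = ", x$statistic,
      ", one-sided p = ", signif(x$p, 4),
      if (x$exact) " (exact)", "\n", sep = "")
  cat("  region medians: ",
      paste(sprintf("%s = %.3g", names(x$region_medians),
                    x$region_medians), collapse = ", "), "\n", sep = "")
  invisible(x)
}
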