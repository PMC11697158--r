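#' Bulk expression cohort with clinical annotations
#'
#' @param log_expr samples x genes matrix of log-CPM expression with
#'   dimnames.
#' @param clinical data.frame with one row per sample: `sample_id`,
#'   `time` (> 0), `event` (0/1), `cancer_type`, and optionally `purity`,
#'   `stage`, `age`, `tissue` ("tumour"/"normal").
#' @return object of class `bulk_cohort`.
#' @export
bulk_cohort <- function(log_expr, clinical) {
  stopifnot(is.matrix(log_expr), !is.null(rownames(log_expr)),
            !is.null(colnames(log_expr)))
  need <- c("sample_id", "time", "event", "cancer_type")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical lacks: ", paste(miss, collapse = ", "))
  clinical <- clinical[match(rownames(log_expr), clinical$sample_id), ,
                       drop = FALSE]
  if (anyNA(clinical$sample_id)) stop("clinical does not cover all samples")
  if (any(clinical$time <= 0)) stop("survival times must be positive")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0/1")
  if (anyNA(clinical$cancer_type)) stop("cancer_type must not be missing")
  rownames(clinical) <- NULL
  structure(list(log_expr = log_expr, clinical = clinical),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat("<bulk_cohort> ", nrow(x$log_expr), " samples x ", ncol(x$log_expr),
      " genes; ", sum(x$clinical$event), " events\n", sep = "")
  invisible(x)
}

#' Per-sample signature Z score
#'
#' Standardises every signature gene across samples (mean 0, sd 1; genes
#' with zero variance are dropped with a warning) and averages the gene
#' Z scores per sample.
#'
#' @param cohort a [bulk_cohort].
#' @param signature `metasig_signature`, [gene_set] or character vector.
#' @return named numeric score vector (one per sample).
#' @export
signature_zscore <- function(cohort, signature) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  genes <- if (inherits(signature, "gene_set")) signature$genes
           else as.character(signature)
  if (nrow(cohort$log_expr) < 2L) stop("need at least 2 samples")
  present <- intersect(genes, colnames(cohort$log_expr))
  if (length(present) == 0L) {
    stop("no signature genes present in the cohort")
  }
  E <- cohort$log_expr[, present, drop = FALSE]
  sds <- apply(E, 2L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped")
    E <- E[, sds > 0, drop = FALSE]
    if (ncol(E) == 0L) stop("all signature genes have zero variance")
  }
  Z <- scale(E)
  out <- rowMeans(Z)
  names(out) <- rownames(cohort$log_expr)
  out
}

#' Median stratification within cancer type
#'
#' Labels each sample high when its score strictly exceeds the median of
#' its own cancer type, low otherwise, so strata are comparable across
#' heterogeneous cohorts.
#'
#' @param scores named numeric vector.
#' @param cancer_type character/factor vector aligned with `scores`.
#' @return character vector of "high"/"low" labels.
#' @export
stratify_median <- function(scores, cancer_type) {
  stopifnot(length(scores) == length(cancer_type))
  lab <- character(length(scores))
  for (ct in unique(cancer_type)) {
    i <- cancer_type == ct
    if (sum(i) < 2L) stop("cancer type '", ct, "' has fewer than 2 samples")
    med <- median(scores[i])
    if (diff(range(scores[i])) == 0) {
      warning("all scores tied within cancer type '", ct, "'; all low")
    }
    lab[i] <- ifelse(scores[i] > med, "high", "low")
  }
  names(lab) <- names(scores)
  lab
}

#' Cox proportional-hazards fit for signature scores
#'
#' Fits a Cox model of survival on the continuous signature score plus
#' clinical covariates, with Breslow tie handling. Cancer type enters as
#' a stratification variable (separate baseline hazards) by default, or
#' as dummy-coded covariates. Wald p-values are Benjamini-Hochberg
#' adjusted across the model's coefficients.
#'
#' @param cohort a [bulk_cohort].
#' @param scores per-sample signature scores (see [signature_zscore()]).
#' @param covariates clinical columns to adjust for.
#' @param type_as one of "strata" (default) or "covariate".
#' @param subset optional logical vector of samples to fit on.
#' @return object of class `metasig_cox`: coefficient table (`beta`, `se`,
#'   `hazard_ratio`, `wald_p`, `adjusted_p`), `n`, `n_events`,
#'   `converged`, and the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(cohort, scores, covariates = c("purity", "stage", "age"),
                    type_as = c("strata", "covariate"), subset = NULL) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  type_as <- match.arg(type_as)
  cl <- cohort$clinical
  df <- data.frame(time = cl$time, event = cl$event,
                   cancer_type = cl$cancer_type, score = as.numeric(scores),
                   stringsAsFactors = FALSE)
  covariates <- intersect(covariates, names(cl))
  for (cv in covariates) df[[cv]] <- cl[[cv]]
  if (!is.null(subset)) df <- df[subset, , drop = FALSE]
  if (sum(df$event) < 10L) stop("need at least 10 events")
  rhs <- c("score", covariates,
           if (type_as == "strata") "strata(cancer_type)" else "cancer_type")
  fm <- as.formula(paste("survival::Surv(time, event) ~",
                         paste(rhs, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fm, data = df, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  if (anyNA(co[, "coef"])) converged <- FALSE
  tab <- data.frame(term = rownames(co), beta = co[, "coef"],
                    se = co[, "se(coef)"],
                    hazard_ratio = exp(co[, "coef"]),
                    wald_p = co[, "Pr(>|z|)"],
                    adjusted_p = p.adjust(co[, "Pr(>|z|)"], "BH"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(coefficients = tab, n = sm$n, n_events = sm$nevent,
                 converged = converged, fit = fit),
            class = "metasig_cox")
}

#' @export
print.metasig_cox <- function(x, ...) {
  cat("<metasig_cox> n = ", x$n, ", events = ", x$n_events,
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.metasig_cox <- function(object, ...) {
  setNames(object$coefficients$beta, object$coefficients$term)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group with right censoring, and
#' the two-sided log-rank statistic against a chi-squared reference.
#'
#' @param time positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param group group labels (>= 2 non-empty groups).
#' @return object of class `km_result`: `curves` (group, time, n_risk,
#'   n_event, surv), `medians`, `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0L)) stop("empty group")
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (sum(event) < 1L) stop("need at least one event")
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  ss <- summary(sf)
  grp <- if (is.null(ss$strata)) rep(levels(group)[1L], length(ss$time))
         else sub("^group=", "", as.character(ss$strata))
  curves <- data.frame(group = grp, time = ss$time, n_risk = ss$n.risk,
                       n_event = ss$n.event, surv = ss$surv,
                       stringsAsFactors = FALSE)
  med <- summary(sf)$table
  medians <- if (is.matrix(med)) setNames(med[, "median"],
                                          sub("^group=", "", rownames(med)))
             else setNames(med["median"], levels(group)[1L])
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_$n) - 1L
  p <- pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  structure(list(curves = curves, medians = medians, chisq = sd_$chisq,
                 df = df, p = p),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result> log-rank chisq = ", signif(x$chisq, 4), " (df ", x$df,
      "), p = ", signif(x$p, 4), "\n", sep = "")
  cat("  median survival: ",
      paste(sprintf("%s = %.3g", names(x$medians), x$medians),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tumour-vs-normal score comparison per cancer type
#'
#' One-sided Wilcoxon rank-sum test (tumour greater) of signature scores
#' within each cancer type having both tissues, Benjamini-Hochberg
#' adjusted across types.
#'
#' @param scores per-sample scores.
#' @param tissue "tumour"/"normal" labels.
#' @param cancer_type cancer type labels.
#' @param q_cut significance level on the adjusted p (default 0.05).
#' @return data.frame (cancer_type, n_tumour, n_normal, p, q) with
#'   attribute `n_significant`.
#' @export
group_compare <- function(scores, tissue, cancer_type, q_cut = 0.05) {
  res <- list()
  for (ct in unique(cancer_type)) {
    i <- cancer_type == ct
    tum <- scores[i & tissue == "tumour"]
    nor <- scores[i & tissue == "normal"]
    if (length(tum) == 0L || length(nor) == 0L) {
      warning("cancer type '", ct, "' lacks a tissue; skipped")
      next
    }
    wt <- suppressWarnings(
      wilcox.test(tum, nor, alternative = "greater"))
    res[[ct]] <- data.frame(cancer_type = ct, n_tumour = length(tum),
                            n_normal = length(nor), p = wt$p.value,
                            stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) stop("no cancer type has both tissues")
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$q < q_cut)
  out
}

#' Point-biserial correlation of score with late stage
#'
#' Pearson correlation between the continuous score and a binary
#' above/below-stage-III indicator.
#'
#' @param scores numeric scores.
#' @param stage_late logical (or 0/1) indicator for late stage.
#' @return correlation coefficient; NA with a warning when scores are
#'   constant or a stage group is absent.
#' @export
stage_correlation <- function(scores, stage_late) {
  stage_late <- as.numeric(stage_late)
  if (length(unique(stage_late)) < 2L) {
    warning("both stage groups must be present")
    return(NA_real_)
  }
  if (diff(range(scores)) == 0) {
    warning("constant scores: correlation undefined")
    return(NA_real_)
  }
  cor(scores, stage_late)
}
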