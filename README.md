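# metasig

Derivation and application of a pan-cancer metastatic gene signature from
multi-patient single-cell RNA-seq.

Metastasis-associated expression programs are shared across cancer types,
but bulk profiling averages them away and single-patient analyses cannot
separate what is conserved from what is idiosyncratic. `metasig` implements
a complete, testable pipeline for the task a pan-cancer single-cell study
faces:

1. **Per-patient archetypal analysis.** Each patient's QC-filtered,
   log-normalised cells are reduced to principal components and decomposed
   into archetypes — every cell a convex combination of a few extreme
   expression programs, every archetype a convex combination of cells
   (principal convex hull analysis, projected-gradient optimisation with a
   furthest-point start).
2. **Rank-based scoring.** Gene-set activity is a Mann–Whitney *U* statistic
   on within-unit expression ranks with a rank cap:
   `score(u) = max(0, 1 − U'(u) / (n_g · r_max))`, bounded in [0, 1] and
   independent of which other cells are present.
3. **Signature derivation.** Archetype gene programs (top footprint genes,
   z-scored loading-weighted means) are scored against seed lists of
   metastasis-associated genes, top-scoring archetypes selected per patient
   and resolution, gene frequencies across selected programs counted, and
   the core signature cut at the knee (inflection point) of the count
   spectrum. A cell-type specificity step (per-tumour mean expression
   proportions, Ward-clustered) refines the core to its
   epithelial-specific part and a stromal residual.
4. **Downstream analyses.** Per-cell staging (16 bins, bottom 20% / middle
   60% / top 20%), pseudobulk differential expression (Welch t on
   log2-CPM, BH adjustment), bulk-cohort survival (signature Z scores,
   within-type median stratification, stratified Cox with Breslow ties,
   Kaplan–Meier and log-rank), spatial-spot scoring with one-sided
   rank-sum region tests, and pseudotime switch-time ordering (logistic
   fits on binarised expression, McFadden pseudo-R², top-50 timeline).

A first-class synthetic-data module generates every input with planted
ground truth — a multi-patient negative-binomial cohort carrying a planted
two-compartment metastatic program, survival-linked bulk cohorts, spatial
slides with an enriched invasive edge, and pseudotime panels with sigmoidal
on/off genes — so every stage is validated by recovery of what was planted.
The packaged 177/109/286-gene signature fixtures are synthetic placeholders
mirroring the published split sizes (see `?packaged_signature`).

## Worked example

```r
library(metasig)

# a synthetic 12-patient, 4-cancer-type cohort with a planted
# 150-gene metastatic program
sim <- simulate_cohort(sim_config(seed = 11))
der <- derive_signature(sim$matrices, sim$seed_sets, seed = 11)
der
#> <metasig_derivation>
#>   core signature:    153 genes (threshold 32)
#>   refined / residual: 75 / 78 genes
#>   patients:          12

# how well was the planted program recovered?
mean(unclass(der$core) %in% sim$truth$program_genes)      # precision 0.98
mean(sim$truth$program_genes %in% unclass(der$core))      # recall    1.00

# score cells and stage them
ln <- lognorm(qc_filter(sim$matrices[[1]]))
stages <- assign_stages(set_score(ln, der$core))
table(stages$category)
#> high  low  mid
#>  300  300  900
```

The derived core contains the planted program at precision 0.98 and full
recall; the refined signature isolates the epithelial-specific half; staging
splits cells 20/60/20 by score. A bulk cohort simulated with hazard
λ·exp(β·score) at β = ln 2 is recovered by `cox_fit()` with β̂ within ±0.1
(hazard ratio ≈ 2).

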