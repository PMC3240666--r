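# progstrat

Two-stage prognosis modelling for surgical cancer cohorts, built around
the design used in hepatocellular carcinoma (HCC) studies: clinical
information first, gene expression second — searched *within* the
clinically defined strata, under leakage-safe nested cross-validation.

## Who this is for

Biostatisticians and computational biologists who need to (a) combine
routinely recorded clinicopathologic parameters with tumor / adjacent
non-tumor expression profiles to predict right-censored outcomes
(overall survival, disease-free survival), and (b) calibrate and
power-check that whole pipeline on synthetic cohorts with planted truth
before touching real data.

## The method

**Stage 1.** Univariate Cox screening of the clinicopathologic
parameters (tumor size, NOTN, AFP, ALBU, venous infiltration, pTNM,
AJCC); significant parameters (Wald p < 0.05) enter a multivariate Cox
model whose centered linear predictor *h* = (x − x̄)′β̂ is each patient's
relative-hazard score, computed by leave-one-out (selection refit per
fold). The median of *h* splits patients into good / poor prognosis
groups, evaluated by log-rank test and Kaplan–Meier curves.

**Stage 2.** Within each stratum, a nested leave-one-out loop: per fold,
univariate Cox screen of every gene on the n−1 training patients →
top-K genes (K = 100, smallest Wald p) → covariance PCA → Cox model on
the top m = 6 component scores → projection of the held-out patient to
obtain their *h*. The pooled *h* is median-split and log-rank tested.
Variants: clinical covariates in the fold models
(`expr_plus_clinical`), and a dual-tissue model (6 PCs per tissue,
12 regressors).

Around the core: robust (Tukey bisquare) residualization of every gene
on age and sex; signature derivation at tiered p cutoffs with
hypergeometric overlap enrichment (fold = kN/|A||B|); a cis-eQTL scan
(±1 Mb, BH at 10% FDR) defining eSNPs; an adjusted per-SNP Cox scan
(α = 0.01) defining cSNPs; eSNP-in-cSNP enrichment with a
randomized-endpoint pseudo-cSNP permutation null.

## Worked example

```r
library(progstrat)
cfg <- sim_config(n_patients = 272, n_genes = 1000, n_snps = 500,
                  eqtl_spec = list(n = 30, effect = 1, cis_bp = 5e4),
                  csnp_spec = list(n = 10, effect = 0.5, on_eqtl_frac = 0.8),
                  seed = 8007)
cohort <- generate_cohort(cfg)
cohort
#> Synthetic prognosis cohort: 272 patients, 1000 genes, 500 SNPs (seed 8007)
#>   censored: survival 66.2%, DFS 46.7%

expr <- robust_residualize(cohort$expr_normal, cohort$clinical)
report <- stratified_pipeline(cohort$clinical, cohort$dfs,
                              list(normal = expr), tissue = "normal",
                              K = 100, m = 6)
report
#> Two-stage stratified prognosis report (tissue: normal, K = 100, m = 6)
#>   clinical split: log-rank p = 3.29e-10
#>   good stratum sub-split: log-rank p = 0.00161 (n = 136)
#>   poor stratum sub-split: log-rank p = 0.442 (n = 136)
```

Reading this: the six clinicopathologic parameters separate the cohort
cleanly (p = 3.3e-10). The generator planted a 100-gene prognostic block
in the good stratum's normal tissue; stage 2 finds it there
(p = 0.0016) and, correctly, finds nothing in the poor stratum
(p = 0.44). Selection works at the gene level too — of the good-stratum
top-100 screen, 99 are planted signature genes — and the cis-eQTL scan
recovers the planted regulatory pairs:

```r
scan <- cis_eqtl_scan(cohort$genotypes$dosage, cohort$genotypes$snp_pos,
                      expr, cohort$genotypes$gene_pos)
esnps_at_fdr(scan, q = 0.10)
#> cis-eQTL pairs at 10% FDR: 32 (p threshold 0.00023)
```

Sub-split p-values from pooled leave-one-out predictors are
anticonservative under the null (the selection step sees the training
outcomes); the vignette quantifies this and the test suite freezes it —
read small sub-split p-values accordingly.

## Layout

- `R/` — synthetic cohort generator, survival primitives, robust
  residualization, the two stage classifiers, enrichment analyses,
  cohort I/O and the `run_all()` orchestrator.
- `src/` — one-covariate Cox Newton–Raphson screener (Rcpp), the
  pipeline's hot path.
- `vignettes/stratified-prognosis.Rmd` — model, assumptions, parameter
  defaults and their rationale, numerical choices, known limitations.
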