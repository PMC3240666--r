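---
title: "Two-stage stratified prognosis modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage stratified prognosis modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Prognosis after curative surgery for hepatocellular carcinoma (HCC) varies
widely. Routinely recorded clinicopathologic parameters — tumor size,
number of tumor nodules (NOTN), serum α-fetoprotein (AFP), serum albumin
(ALBU), venous infiltration and tumor stage (pTNM, AJCC) — predict part of
that variation. Gene expression measured in the resected tumor or in
adjacent non-tumor ("normal") liver tissue may carry additional signal,
but a naive genome-wide search mostly rediscovers genes correlated with
the clinical parameters and adds no predictive value. `progstrat`
implements the two-stage design that addresses this: condition on the
clinical information first, then search for expression signal *within*
the clinically defined strata.

## The model and procedure

**Stage 1 (clinical stratification).** Candidate clinicopathologic
parameters are screened one at a time by univariate Cox proportional-
hazards regression against the endpoint (overall survival or disease-free
survival, both right-censored). Parameters with two-sided Wald `p < 0.05`
enter a multivariate Cox model whose centered linear predictor
`h = (x - x̄)'β` is the patient's relative-hazard score. `h` is computed
by leave-one-out (LOO): for each patient, selection *and* the multivariate
fit are redone on the other `n − 1` patients, and the held-out patient is
scored by that model. Patients are dichotomized at the median of `h`
(ties to the good side) into good and poor prognosis groups, and the split
is evaluated by the Mantel–Haenszel log-rank test and Kaplan–Meier curves.

**Stage 2 (within-stratum expression sub-classification).** Within each
stratum, a nested LOO loop runs the full recipe per fold: (i) univariate
Cox screen of every gene on the `n − 1` training patients (optionally with
the clinical covariates' linear predictor as an offset); (ii) selection of
the `K = 100` genes with smallest Wald p, ties broken by gene id;
(iii) covariance PCA of the selected genes (training-mean centered, not
rescaled); (iv) a Cox model on the top `m = 6` component scores (plus the
clinical covariates in combined mode); (v) projection of the held-out
patient onto the training PC basis and evaluation of their `h`. After `n`
folds the pooled `h` is median-split and log-rank tested, exactly as in
stage 1. A dual-tissue variant screens and compresses each tissue
independently per fold and fits the Cox model on the combined `2m = 12`
scores. K = 100 and m = 6 are the conventional operating point (the top
six components typically explain ~80% of the variance of the selected
panel); sensitivity runs with K ∈ {50, 200} and m = 5 give concordant
splits on planted-signal cohorts (label agreement ≥ 0.7 in the test
suite).

**Expression preprocessing.** Each gene is residualized on age and sex
with a robust linear model (M-estimation, Tukey bisquare, tuning constant
4.685 for 95% Gaussian efficiency, MAD scale re-estimated each IRLS
iteration). The residuals are the expression traits used everywhere
downstream; a single gross outlier receives weight zero and cannot drag
the fit. Residualization is applied once on the full cohort before any
cross-validation — the same order as the original design. This is a
potential (mild) leakage source: age/sex coefficients see all patients.
It affects two nuisance covariates per gene, not the outcome, and is
retained for fidelity.

**Enrichment analyses.** Prognosis signatures are derived at tiered
cutoffs (2e-6 ≈ Bonferroni genome-wide; 5e-4 and 0.05 as liberal tiers;
0.01 for membership display) and compared with external gene lists by
overlap: fold enrichment `k·N/(|A|·|B|)` and the one-sided upper-tail
hypergeometric p over a configurable universe (default: genes screened in
this study; symbols matched case-insensitively, no alias resolution).
Genetics: a cis-eQTL scan (simple linear regression of expression on
additive dosage for every SNP within ±1 Mb of the TSS) with
Benjamini–Hochberg control at 10% FDR defines eSNPs; a per-SNP Cox scan
adjusted for the clinical parameters at α = 0.01 defines cSNPs; their
overlap is tested hypergeometrically, and a randomized-endpoint
permutation (time/event pairs permuted jointly, preserving the censoring
marginal) yields pseudo-cSNPs whose enrichment folds form an empirical
null centered at 1.

## The synthetic-cohort generator

The generator (`sim_config()`, `generate_cohort()`) emulates the study
conditions the analysis assumes, with planted truth for every layer:

* **Cohort**: 272 patients; covariate marginals chosen to be realistic
  for a surgical HCC series (age ~ N(55, 11²) years clamped to 18–85,
  85% male, tumor size and AFP log-normal, NOTN = 1 + Poisson(0.7),
  albumin ~ N(40, 5²) g/L, venous infiltration 40%, ordinal pTNM with
  AJCC generated as a correlated stage so the two are collinear, as in
  real registries).
* **Survival**: Weibull(shape 1.2, scale 90 months) baseline ×
  `exp(x'β + SNP effects + z)`, with `z` a shared N(0, 1) frailty — the
  latent prognosis component that expression can see but clinical
  parameters cannot. Censoring is independent uniform(0, c_max) with
  c_max calibrated by bisection so the expected censored fraction matches
  the cohort's observed values: 67.8% for overall survival, 48.9% for DFS
  (51.1% recurrence). Both endpoints share the frailty.
* **Expression**: genes × patients noise with block correlation 0.2
  (blocks of 50). Planted signature blocks (default: one 100-gene block
  per tissue, in the good stratum defined by the median of the true
  clinical linear predictor) receive an additive shift `effect × z` only
  for stratum patients — prognostic signal orthogonal to clinical
  information, the structure the two-stage design exists to find. The
  default per-gene effect is 2.0 noise-SD per unit frailty with
  within-block correlation 0.3. That default was fixed by a design-phase
  power analysis: the event count of a ~115-patient stratum (~25 for
  survival, ~44 for DFS) bounds the power of the sub-split, and 2.0 is
  the regime in which the planted signature is reliably recoverable
  (median 99/100 among the top-100, sub-split p < 0.01 in ~90% of DFS
  replicates) — i.e., a strongly prognostic signature, the setting the
  method targets. Per-gene age/sex nuisance effects are added to every
  gene, and 0.2% of cells are contaminated with ±(6–10) SD spikes to
  exercise the bisquare weights.
* **Genotypes**: Hardy–Weinberg dosages at MAF ~ U(0.05, 0.5),
  independent SNPs on one synthetic chromosome (genes every 100 kb).
  Planted cis-eQTLs (1 expression-SD per allele, within 50 kb of the
  target TSS, applied in adjacent-normal tissue where the genotyping DNA
  originates) and planted outcome SNPs (0.4 log-hazard per allele by
  default, half placed on eQTL SNPs so eSNP/cSNP enrichment carries true
  signal).

What the generator does **not** emulate: probe-level microarray
artifacts/RMA, linkage disequilibrium, population structure, batch
effects, or informative censoring. Passing tests therefore demonstrate
the statistical machinery under the declared generative model, not
robustness to those real-data complications.

## Numerical choices

* Cox ties: Efron approximation by default (Breslow selectable); the
  per-gene screen uses a dedicated one-covariate Newton–Raphson with
  step-halving, |β| ≤ 20 divergence guard, and convergence at
  |score| < 1e-7 or coefficient change < 1e-8; it matches `coxph` to
  machine precision in the tests. Degenerate or non-converged features
  get the sentinel p = 1 (vector lengths stay aligned for ranking).
* Adjusted screens fix the adjustment covariates' Cox linear predictor
  (fit per fold, leakage-safe) as an offset rather than refitting the
  joint model per feature: with features independent of the adjustment
  covariates this is equivalent at screening precision and keeps the
  nested LOO tractable.
* PCA: covariance (not correlation) PCA on residualized traits, which
  are already variance-comparable; loadings' signs fixed so the
  largest-|entry| coordinate is positive (reproducibility only — `h` is
  invariant). `m` is reduced to the matrix rank with a warning. Held-out
  samples are centered by training means.
* Degenerate folds: the PC-Cox fit falls back from m to m−1, …, 1
  components, then to the `h = 0` sentinel, so every patient stays
  labeled and the log-rank remains computable.
* Dichotomization: median split, ties to the good group; an all-equal
  `h` is a degenerate-split error.
* BH step-up threshold is the largest p(i) ≤ i·q/m; discoveries are
  `p ≤ threshold` (reproduces the step-up set exactly; cross-checked
  against `p.adjust`).
* Collinear stage covariates (pTNM/AJCC) may both enter stage 1; if the
  information matrix is singular the dropped coefficient is treated as
  zero in the linear predictor.

## Known limitations

**Pooled leave-one-out predictors are anticonservative under the null.**
The sub-split log-rank test treats the pooled LOO `h` as if it were an
external predictor. It is not: per-fold gene selection encodes the `n−1`
training outcomes, folds share `n−2` patients, and the pooled labels are
therefore jointly dependent on the very outcomes being tested. With pure
noise expression (n = 60, G = 2000, K = 100, m = 6) the nested sub-split
rejects at ~0.2–0.3 instead of 0.05. The package's test suite quantifies
this and the contrast that motivates nesting: a deliberately leaky
variant (selection once on all n) rejects at ~1.0 under the same null;
per-fold selection removes most — but demonstrably not all — of the
selection optimism. The same caveat applies in attenuated form to the
stage-1 clinical LOO. Mechanistically this is the classic pre-validation
problem (outcome-blind selection through the identical machinery is
calibrated at ~0.03–0.05 in the suite); a permutation reference for the
sub-split p-value would restore calibration and is a natural extension.
Reported sub-split p-values should be read with this in mind.

**Other limitations.** Residualization before cross-validation (above);
no time-varying covariates, stratified baselines or frailty models in the
fitters; symbol-level gene matching only; the eQTL scan is a simple
per-pair regression (no mixed models, no LD-aware clumping); permutation
count for the pseudo-cSNP null defaults to 20, giving an empirical p
floor of 1/21.

## Problem sizes in the tests

The acceptance suite runs at desk scale, chosen as the package's own
operating sizes: 200 pure-noise cohorts (n = 60, G = 2000) for the
leakage study; 50 planted-signature replicates (n = 230, G = 1500, DFS
endpoint, evaluated within the planted strata); 50 eQTL-FDR replicates
(n = 150, 100 genes × 400 SNPs); one permutation-null cohort (n = 250,
3000 SNPs, 30 permutations); 2000 log-rank null replicates (n = 200); 200
brute-force Cox comparisons (n ≤ 8). `scripts/acceptance.R` reruns the
full pipeline on one 272-patient cohort and writes its headline numbers
as JSON.
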