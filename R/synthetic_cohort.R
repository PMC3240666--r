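#' Simulation configuration for synthetic prognosis cohorts
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults
#' emulate the study conditions of a surgical hepatocellular-carcinoma
#' cohort: 272 patients, ~67.8% right-censoring for overall survival and
#' ~48.9% for disease-free survival, six prognostic clinicopathologic
#' parameters, stratum-specific 100-gene prognostic expression blocks, and
#' genotypes carrying planted cis-eQTLs and outcome-associated SNPs.
#'
#' @param n_patients,n_genes,n_snps cohort dimensions (all > 0).
#' @param clinical_effects named log-hazard coefficients on columns of
#'   [clinical_design()]; these define the true clinical linear predictor.
#' @param frailty_sd standard deviation of the shared lognormal-frailty
#'   term: a latent per-patient log-hazard component that drives both
#'   endpoints and the planted expression signal (so expression carries
#'   prognostic information beyond the clinical parameters).
#' @param signature_spec list of planted signature blocks; each entry is a
#'   list with `stratum` ("good"/"poor", defined by the median of the true
#'   clinical linear predictor), `tissue` ("tumor"/"normal"), `size` (gene
#'   count), `effect` (per-gene expression shift per unit frailty, in noise
#'   SD units) and `rho` (within-block correlation, < 1).
#' @param censoring_target,dfs_censoring_target expected censored fraction
#'   for the survival and DFS endpoints, strictly inside (0, 1).
#' @param baseline_shape,baseline_scale Weibull baseline hazard (months).
#' @param nuisance list: `age_sd`/`sex_sd` (SD of per-gene age and sex
#'   expression effects) and `outlier_rate` (fraction of expression cells
#'   contaminated by 6-10 SD spikes, exercising the bisquare weights).
#' @param eqtl_spec list: `n` planted cis-eQTLs, `effect` (expression SD per
#'   allele, applied in adjacent-normal tissue), `cis_bp` (max SNP-TSS
#'   distance of planted pairs).
#' @param csnp_spec list: `n` planted outcome SNPs, `effect` (log-hazard per
#'   allele), `on_eqtl_frac` (fraction of planted cSNPs placed on eQTL SNPs
#'   so that eSNP/cSNP enrichment carries true signal).
#' @param noise_rho,noise_block background block correlation of
#'   non-signature genes and block size.
#' @param maf_range minor-allele-frequency range for simulated SNPs.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 272L, n_genes = 2000L, n_snps = 2000L,
                       clinical_effects = c(log_tumor_size = 0.5,
                                            notn = 0.3,
                                            log_afp = 0.18,
                                            albu = -0.06,
                                            venous_infiltration = 0.5,
                                            ptnm = 0.3),
                       frailty_sd = 1.0,
                       signature_spec = list(
                         list(stratum = "good", tissue = "normal",
                              size = 100L, effect = 2.0, rho = 0.3),
                         list(stratum = "good", tissue = "tumor",
                              size = 100L, effect = 2.0, rho = 0.3)),
                       censoring_target = 0.678,
                       dfs_censoring_target = 0.489,
                       baseline_shape = 1.2, baseline_scale = 90,
                       nuisance = list(age_sd = 0.01, sex_sd = 0.3,
                                       outlier_rate = 0.002),
                       eqtl_spec = list(n = 50L, effect = 1.0,
                                        cis_bp = 50000L),
                       csnp_spec = list(n = 20L, effect = 0.4,
                                        on_eqtl_frac = 0.5),
                       noise_rho = 0.2, noise_block = 50L,
                       maf_range = c(0.05, 0.5),
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes), n_snps = as.integer(n_snps),
              clinical_effects = clinical_effects, frailty_sd = frailty_sd,
              signature_spec = signature_spec,
              censoring_target = censoring_target,
              dfs_censoring_target = dfs_censoring_target,
              baseline_shape = baseline_shape,
              baseline_scale = baseline_scale,
              nuisance = nuisance, eqtl_spec = eqtl_spec,
              csnp_spec = csnp_spec, noise_rho = noise_rho,
              noise_block = as.integer(noise_block),
              maf_range = maf_range, seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field)
    if (!isTRUE(ok)) ps_stop(paste0("invalid config field: ", field),
                             "config_error")
  chk(cfg$n_patients > 0L, "n_patients")
  chk(cfg$n_genes > 0L, "n_genes")
  chk(cfg$n_snps > 0L, "n_snps")
  chk(cfg$censoring_target > 0 && cfg$censoring_target < 1,
      "censoring_target")
  chk(cfg$dfs_censoring_target > 0 && cfg$dfs_censoring_target < 1,
      "dfs_censoring_target")
  chk(cfg$baseline_shape > 0, "baseline_shape")
  chk(cfg$baseline_scale > 0, "baseline_scale")
  chk(cfg$frailty_sd >= 0, "frailty_sd")
  chk(cfg$noise_rho >= 0 && cfg$noise_rho < 1, "noise_rho")
  chk(cfg$noise_block > 0L, "noise_block")
  chk(length(cfg$maf_range) == 2L && cfg$maf_range[1] > 0 &&
        cfg$maf_range[2] <= 0.5, "maf_range")
  chk(cfg$nuisance$outlier_rate >= 0 && cfg$nuisance$outlier_rate < 1,
      "nuisance$outlier_rate")
  for (s in cfg$signature_spec) {
    chk(s$stratum %in% c("good", "poor"), "signature_spec$stratum")
    chk(s$tissue %in% c("tumor", "normal"), "signature_spec$tissue")
    chk(s$size > 0, "signature_spec$size")
    chk(s$rho >= 0 && s$rho < 1, "signature_spec$rho")
  }
  tot <- sum(vapply(cfg$signature_spec, function(s) as.integer(s$size),
                    integer(1)))
  chk(tot <= cfg$n_genes, "signature_spec (total size exceeds n_genes)")
  chk(cfg$eqtl_spec$n <= cfg$n_snps, "eqtl_spec$n")
  chk(cfg$csnp_spec$n <= cfg$n_snps, "csnp_spec$n")
  chk(length(cfg$seed) == 1L && is.finite(cfg$seed), "seed")
  class(cfg) <- "sim_config"
  cfg
}

# marginal distributions of the simulated clinicopathologic covariates;
# single source of truth shared by the generator and its calibration tests
clinical_marginals <- function() {
  list(age = list(mean = 55, sd = 11, lo = 18, hi = 85),
       sex_p_male = 0.85,
       tumor_size = list(meanlog = log(5), sdlog = 0.6),
       notn = list(base = 1, lambda = 0.7),
       afp = list(meanlog = log(100), sdlog = 2.5),
       albu = list(mean = 40, sd = 5),
       venous_p = 0.4,
       ptnm_probs = c(0.25, 0.35, 0.30, 0.10))
}

#' Generate a clinicopathologic table
#'
#' Draws the per-patient covariates from the declared marginals (see
#' `progstrat:::clinical_marginals`): age normal (clamped to 18-85 years),
#' sex male-skewed, tumor size and AFP log-normal (heavy-tailed markers),
#' number of tumor nodules 1 + Poisson, albumin normal, venous infiltration
#' Bernoulli, pTNM ordinal multinomial and AJCC an ordinal stage correlated
#' with pTNM (collinear stage variables, as in real cohorts).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to the config seed (stage offset 1).
#' @return A `data.frame` with one row per patient.
#' @export
generate_clinical <- function(config, seed = config$seed + 1L) {
  config <- validate_config(config)
  n <- config$n_patients
  m <- clinical_marginals()
  with_seed(seed, {
    age <- pmin(pmax(rnorm(n, m$age$mean, m$age$sd), m$age$lo), m$age$hi)
    sex <- ifelse(runif(n) < m$sex_p_male, "M", "F")
    tumor_size <- exp(rnorm(n, m$tumor_size$meanlog, m$tumor_size$sdlog))
    notn <- m$notn$base + rpois(n, m$notn$lambda)
    afp <- exp(rnorm(n, m$afp$meanlog, m$afp$sdlog))
    albu <- rnorm(n, m$albu$mean, m$albu$sd)
    venous <- as.integer(runif(n) < m$venous_p)
    ptnm <- sample(seq_along(m$ptnm_probs), n, replace = TRUE,
                   prob = m$ptnm_probs)
    ajcc <- pmin(length(m$ptnm_probs),
                 pmax(1L, ptnm + sample(c(-1L, 0L, 1L), n, replace = TRUE,
                                        prob = c(0.15, 0.7, 0.15))))
    data.frame(patient_id = sprintf("P%04d", seq_len(n)),
               age = age, sex = sex, tumor_size = tumor_size, notn = notn,
               afp = afp, albu = albu, venous_infiltration = venous,
               ptnm = ptnm, ajcc = ajcc, stringsAsFactors = FALSE)
  })
}

#' Numeric design matrix of clinicopathologic covariates
#'
#' Encodes the clinical table for Cox modelling: age in years, sex as a
#' male indicator, tumor size and AFP on the log scale (heavy-tailed
#' markers), and the remaining parameters as recorded. Row names are
#' patient ids.
#'
#' @param clinical a clinical table as from [generate_clinical()].
#' @return Numeric matrix, patients x 9 covariates.
#' @export
clinical_design <- function(clinical) {
  X <- cbind(age = as.numeric(clinical$age),
             sex = as.numeric(clinical$sex == "M"),
             log_tumor_size = log(as.numeric(clinical$tumor_size)),
             notn = as.numeric(clinical$notn),
             log_afp = log(as.numeric(clinical$afp)),
             albu = as.numeric(clinical$albu),
             venous_infiltration = as.numeric(clinical$venous_infiltration),
             ptnm = as.numeric(clinical$ptnm),
             ajcc = as.numeric(clinical$ajcc))
  rownames(X) <- clinical$patient_id
  X
}

# true clinical log-hazard (centered); defines the planted strata
true_clinical_lp <- function(clinical, config) {
  X <- clinical_design(clinical)
  eff <- config$clinical_effects
  missing_cols <- setdiff(names(eff), colnames(X))
  if (length(missing_cols))
    ps_stop(paste0("clinical_effects name unknown covariates: ",
                   paste(missing_cols, collapse = ", ")), "config_error")
  Xe <- X[, names(eff), drop = FALSE]
  eta <- drop(Xe %*% eff)
  eta - mean(eta)
}

# good stratum = lower true clinical hazard (ties to good)
true_stratum <- function(clinical, config) {
  eta <- true_clinical_lp(clinical, config)
  ifelse(eta <= median(eta), "good", "poor")
}

#' Generate genotypes with planted cis-eQTLs and outcome SNPs
#'
#' Draws Hardy-Weinberg additive dosages at uniform minor-allele
#' frequencies, places genes along one synthetic chromosome (TSS every
#' 100 kb) and SNPs uniformly over the same span. Planted eQTL SNPs are
#' repositioned within `eqtl_spec$cis_bp` of their target gene's TSS; their
#' expression effects are applied later by [generate_expression()]. Planted
#' cSNP log-hazard effects are applied by [generate_survival()] via
#' `extra_loghazard` (the orchestrator [generate_cohort()] enforces this
#' order).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (stage offset 2).
#' @return List: `dosage` (SNPs x patients, values 0/1/2), `snp_pos`,
#'   `gene_pos` (position tables), `maf`, and `truth` (planted eQTL pairs
#'   and cSNP effects).
#' @export
generate_genotypes <- function(config, seed = config$seed + 2L) {
  config <- validate_config(config)
  n <- config$n_patients; M <- config$n_snps; G <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(G))
  snp_ids <- sprintf("S%05d", seq_len(M))
  span <- G * 100000 + 1000000
  with_seed(seed, {
    gene_pos <- data.frame(gene = gene_ids, chrom = "1",
                           tss = seq_len(G) * 100000,
                           stringsAsFactors = FALSE)
    snp_bp <- sort(sample.int(span, M, replace = FALSE))
    maf <- runif(M, config$maf_range[1], config$maf_range[2])
    dosage <- matrix(rbinom(M * n, 2L, rep(maf, n)), nrow = M, ncol = n)
    rownames(dosage) <- snp_ids
    colnames(dosage) <- sprintf("P%04d", seq_len(n))

    # signature genes are reserved for the expression planting; eQTL
    # targets come from the remaining genes so truth records stay disjoint
    sig_total <- sum(vapply(config$signature_spec,
                            function(s) as.integer(s$size), integer(1)))
    free_genes <- setdiff(seq_len(G), seq_len(sig_total))
    n_eqtl <- as.integer(config$eqtl_spec$n)
    eqtl <- NULL
    if (n_eqtl > 0L) {
      if (length(free_genes) < n_eqtl)
        ps_stop("not enough non-signature genes for planted eQTLs",
                "generation_error")
      tgt <- sample(free_genes, n_eqtl)
      esnp_idx <- sample.int(M, n_eqtl)
      # replant each eQTL SNP inside the cis window of its target gene
      snp_bp[esnp_idx] <- pmax(1, gene_pos$tss[tgt] +
        round(runif(n_eqtl, -config$eqtl_spec$cis_bp,
                    config$eqtl_spec$cis_bp)))
      eqtl <- data.frame(snp = snp_ids[esnp_idx], gene = gene_ids[tgt],
                         effect = config$eqtl_spec$effect,
                         stringsAsFactors = FALSE)
    }
    n_csnp <- as.integer(config$csnp_spec$n)
    csnp <- NULL
    if (n_csnp > 0L) {
      n_on <- min(n_eqtl, round(n_csnp * config$csnp_spec$on_eqtl_frac))
      idx_on <- if (n_on > 0L) sample(match(eqtl$snp, snp_ids), n_on)
                else integer(0)
      pool <- setdiff(seq_len(M), idx_on)
      idx_off <- sample(pool, n_csnp - n_on)
      csnp <- data.frame(snp = snp_ids[c(idx_on, idx_off)],
                         effect = config$csnp_spec$effect,
                         stringsAsFactors = FALSE)
    }
    snp_pos <- data.frame(snp = snp_ids, chrom = "1", bp = snp_bp,
                          stringsAsFactors = FALSE)
    list(dosage = dosage, snp_pos = snp_pos, gene_pos = gene_pos,
         maf = maf, truth = list(eqtl = eqtl, csnp = csnp))
  })
}

#' Generate right-censored survival times from a proportional-hazards model
#'
#' Event times are drawn by inverse-CDF sampling from a Weibull baseline
#' scaled by `exp(eta)`, where `eta` is the true clinical linear predictor
#' plus the shared frailty plus any planted SNP log-hazard term. Censoring
#' is independent uniform on `(0, c_max)` with `c_max` calibrated by
#' bisection so the expected censored fraction equals `censoring_target`.
#'
#' @param clinical table from [generate_clinical()].
#' @param config a [sim_config()].
#' @param extra_loghazard optional per-patient additive log-hazard (e.g.
#'   planted cSNP effects).
#' @param frailty optional shared latent log-hazard vector; drawn
#'   `N(0, frailty_sd)` if `NULL`.
#' @param censoring_target expected censored fraction for this endpoint.
#' @param seed RNG seed (stage offset 3).
#' @return List with `outcome` (a [survival_outcome()]) and `truth`
#'   (true coefficients, frailty, realized censored fraction, `c_max`).
#' @export
generate_survival <- function(clinical, config, extra_loghazard = NULL,
                              frailty = NULL,
                              censoring_target = config$censoring_target,
                              seed = config$seed + 3L) {
  config <- validate_config(config)
  n <- nrow(clinical)
  eta_clin <- true_clinical_lp(clinical, config)
  if (is.null(extra_loghazard)) extra_loghazard <- rep(0, n)
  with_seed(seed, {
    if (is.null(frailty)) frailty <- rnorm(n, 0, config$frailty_sd)
    eta <- eta_clin + extra_loghazard + frailty
    eta <- eta - mean(eta)
    u <- runif(n)
    T <- config$baseline_scale * (-log(u) / exp(eta))^(1 / config$baseline_shape)
    cmax <- calibrate_censoring(T, censoring_target)
    C <- runif(n, 0, cmax)
    time <- pmax(pmin(T, C), 1e-8)
    event <- as.integer(T <= C)
    outcome <- survival_outcome(clinical$patient_id, time, event)
    list(outcome = outcome,
         truth = list(clinical_effects = config$clinical_effects,
                      frailty = setNames(frailty, clinical$patient_id),
                      extra_loghazard = extra_loghazard,
                      censoring_target = censoring_target,
                      censoring_realized = mean(event == 0L),
                      c_max = cmax))
  })
}

# bisection for the uniform-censoring upper bound: conditional on the
# drawn event times T, the expected censored fraction is
# mean(pmin(T / c_max, 1)), monotone decreasing in c_max
calibrate_censoring <- function(T, target) {
  f <- function(cmax) mean(pmin(T / cmax, 1))
  lo <- min(T) * 1e-6
  hi <- max(T) * 2
  it <- 0L
  while (f(hi) > target && it < 200L) { hi <- hi * 2; it <- it + 1L }
  if (f(hi) > target || f(lo) < target)
    ps_stop("censoring calibration failed to bracket the target",
            "calibration_error")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate tumor and adjacent-normal expression matrices
#'
#' Non-signature genes are standard-normal noise with block correlation
#' `noise_rho` (consecutive blocks of `noise_block` genes share a latent
#' factor). Signature genes additionally receive, only for patients in the
#' configured stratum and only in the configured tissue, an additive shift
#' `effect * frailty` -- coupling their expression to the patient's latent
#' prognosis beyond the clinical parameters. Planted eQTL dosage effects
#' are added to their target gene in the adjacent-normal tissue. All genes
#' receive per-gene age/sex nuisance effects, and a small fraction of cells
#' is contaminated with 6-10 SD outliers.
#'
#' @param clinical table from [generate_clinical()].
#' @param config a [sim_config()].
#' @param frailty shared latent log-hazard vector (from
#'   [generate_survival()] truth).
#' @param genotypes optional result of [generate_genotypes()] whose planted
#'   eQTL effects are applied.
#' @param seed RNG seed (stage offset 5).
#' @return List: `tumor`, `normal` (genes x patients matrices) and `truth`
#'   (per-block signature gene ids, strata, effects).
#' @export
generate_expression <- function(clinical, config, frailty,
                                genotypes = NULL,
                                seed = config$seed + 5L) {
  config <- validate_config(config)
  n <- nrow(clinical); G <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(G))
  stratum <- true_stratum(clinical, config)
  nz <- config$nuisance
  age_c <- clinical$age - mean(clinical$age)
  sex01 <- as.numeric(clinical$sex == "M")

  make_tissue <- function(tissue) {
    blocks <- rep(seq_len(ceiling(G / config$noise_block)),
                  each = config$noise_block)[seq_len(G)]
    fac <- matrix(rnorm(max(blocks) * n), nrow = max(blocks))
    E <- sqrt(config$noise_rho) * fac[blocks, , drop = FALSE] +
      sqrt(1 - config$noise_rho) * matrix(rnorm(G * n), nrow = G)
    # planted stratum-specific signal
    start <- 1L
    sig <- list()
    for (s in config$signature_spec) {
      idx <- seq.int(start, start + s$size - 1L)
      start <- start + as.integer(s$size)
      blk_f <- rnorm(n)
      E[idx, ] <- sqrt(s$rho) * matrix(blk_f, nrow = s$size, ncol = n,
                                       byrow = TRUE) +
        sqrt(1 - s$rho) * matrix(rnorm(s$size * n), nrow = s$size)
      if (s$tissue == tissue) {
        in_str <- stratum == s$stratum
        if (any(in_str))
          E[idx, in_str] <- E[idx, in_str] +
            matrix(s$effect * frailty[in_str], nrow = length(idx),
                   ncol = sum(in_str), byrow = TRUE)
        sig[[length(sig) + 1L]] <-
          list(tissue = tissue, stratum = s$stratum,
               genes = gene_ids[idx], effect = s$effect, rho = s$rho)
      }
    }
    # cis-eQTL dosage effects act in the adjacent-normal tissue, where the
    # genotyping DNA originates
    if (tissue == "normal" && !is.null(genotypes) &&
        !is.null(genotypes$truth$eqtl)) {
      eq <- genotypes$truth$eqtl
      gi <- match(eq$gene, gene_ids)
      si <- match(eq$snp, rownames(genotypes$dosage))
      for (k in seq_len(nrow(eq)))
        E[gi[k], ] <- E[gi[k], ] + eq$effect[k] * genotypes$dosage[si[k], ]
    }
    # age/sex nuisance on every gene
    a_g <- rnorm(G, 0, nz$age_sd)
    s_g <- rnorm(G, 0, nz$sex_sd)
    E <- E + outer(a_g, age_c) + outer(s_g, sex01)
    # gross outliers
    if (nz$outlier_rate > 0) {
      n_out <- rbinom(1L, G * n, nz$outlier_rate)
      if (n_out > 0L) {
        cells <- sample.int(G * n, n_out)
        E[cells] <- E[cells] +
          sample(c(-1, 1), n_out, replace = TRUE) * runif(n_out, 6, 10)
      }
    }
    dimnames(E) <- list(gene_ids, clinical$patient_id)
    list(E = E, sig = sig)
  }

  with_seed(seed, {
    tum <- make_tissue("tumor")
    nor <- make_tissue("normal")
    list(tumor = tum$E, normal = nor$E,
         truth = list(signature = c(tum$sig, nor$sig),
                      stratum = setNames(stratum, clinical$patient_id)))
  })
}

#' Generate a complete synthetic cohort with planted truth
#'
#' Orchestrates the sub-generators in the order their dependencies require:
#' clinical covariates, genotypes (cSNP effects must exist before survival
#' times are drawn), shared frailty + survival and DFS outcomes, then
#' expression with stratum-specific planted signal and eQTL effects.
#'
#' @param config a [sim_config()].
#' @return List of class `synthetic_cohort`: `clinical`, `survival`, `dfs`,
#'   `expr_tumor`, `expr_normal`, `genotypes` (dosage + positions), `truth`
#'   (all planted parameters) and the `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  config <- validate_config(config)
  clinical <- generate_clinical(config)
  geno <- generate_genotypes(config)
  extra <- rep(0, nrow(clinical))
  if (!is.null(geno$truth$csnp)) {
    si <- match(geno$truth$csnp$snp, rownames(geno$dosage))
    extra <- drop(crossprod(geno$dosage[si, , drop = FALSE],
                            geno$truth$csnp$effect))
  }
  surv <- generate_survival(clinical, config, extra_loghazard = extra,
                            seed = config$seed + 3L)
  dfs <- generate_survival(clinical, config, extra_loghazard = extra,
                           frailty = surv$truth$frailty,
                           censoring_target = config$dfs_censoring_target,
                           seed = config$seed + 4L)
  expr <- generate_expression(clinical, config,
                              frailty = surv$truth$frailty,
                              genotypes = geno)
  truth <- list(clinical_effects = config$clinical_effects,
                frailty = surv$truth$frailty,
                stratum = expr$truth$stratum,
                signature = expr$truth$signature,
                eqtl = geno$truth$eqtl, csnp = geno$truth$csnp,
                censoring_realized = surv$truth$censoring_realized,
                dfs_censoring_realized = dfs$truth$censoring_realized)
  structure(list(clinical = clinical, survival = surv$outcome,
                 dfs = dfs$outcome, expr_tumor = expr$tumor,
                 expr_normal = expr$normal,
                 genotypes = list(dosage = geno$dosage,
                                  snp_pos = geno$snp_pos,
                                  gene_pos = geno$gene_pos),
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic prognosis cohort: ", nrow(x$clinical), " patients, ",
      nrow(x$expr_tumor), " genes, ", nrow(x$genotypes$dosage),
      " SNPs (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  censored: survival %.1f%%, DFS %.1f%%\n",
              100 * x$truth$censoring_realized,
              100 * x$truth$dfs_censoring_realized))
  invisible(x)
}
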