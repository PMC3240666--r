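test_that("configuration is validated with field-naming errors", {
  expect_error(sim_config(n_patients = 0), class = "config_error")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(censoring_target = 1), "censoring_target")
  expect_error(sim_config(noise_rho = 1), "noise_rho")
  expect_error(sim_config(n_genes = 50,
                          signature_spec = list(list(stratum = "good",
                            tissue = "tumor", size = 100, effect = 1,
                            rho = 0.2))),
               "signature_spec")
  expect_error(sim_config(n_snps = 5,
                          eqtl_spec = list(n = 10, effect = 1,
                                           cis_bp = 5e4)),
               "eqtl_spec")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 7L)
  expect_identical(generate_clinical(cfg), generate_clinical(cfg))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$expr_tumor, c2$expr_tumor)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  # different seeds give different planted truth
  c3 <- generate_cohort(small_config(seed = 8L))
  expect_false(identical(c1$truth$frailty, c3$truth$frailty))
  expect_false(identical(c1$truth$eqtl$snp, c3$truth$eqtl$snp))
})

test_that("clinical covariates match their configured marginals", {
  cfg <- sim_config(n_patients = 5000, n_genes = 10, n_snps = 10,
                    signature_spec = list(),
                    eqtl_spec = list(n = 2, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 2, effect = 0, on_eqtl_frac = 0),
                    seed = 5L)
  cl <- generate_clinical(cfg)
  m <- progstrat:::clinical_marginals()
  n <- nrow(cl)
  within3se <- function(x, mean, sd)
    expect_lt(abs(mean(x) - mean), 3 * sd / sqrt(n))
  within3se(cl$age, m$age$mean, m$age$sd)
  within3se(log(cl$tumor_size), m$tumor_size$meanlog, m$tumor_size$sdlog)
  within3se(log(cl$afp), m$afp$meanlog, m$afp$sdlog)
  within3se(cl$notn, m$notn$base + m$notn$lambda, sqrt(m$notn$lambda))
  within3se(cl$albu, m$albu$mean, m$albu$sd)
  within3se(cl$venous_infiltration, m$venous_p,
            sqrt(m$venous_p * (1 - m$venous_p)))
  within3se(as.numeric(cl$sex == "M"), m$sex_p_male,
            sqrt(m$sex_p_male * (1 - m$sex_p_male)))
  expect_false(anyDuplicated(cl$patient_id) > 0)
})

test_that("censoring calibration hits the cohort's target fraction", {
  cfg <- sim_config(n_patients = 2000, n_genes = 10, n_snps = 10,
                    signature_spec = list(),
                    eqtl_spec = list(n = 0, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 0, effect = 0, on_eqtl_frac = 0),
                    seed = 6L)
  cl <- generate_clinical(cfg)
  sv <- generate_survival(cl, cfg)
  # default target is the cohort's 67.8% right-censored fraction
  expect_equal(cfg$censoring_target, 0.678)
  expect_lt(abs(sv$truth$censoring_realized - 0.678), 0.04)
  expect_true(all(sv$outcome$time > 0))
})

test_that("planted proportional-hazards effects are recovered by Cox", {
  # single binary covariate with beta = ln 2, no frailty: the multivariate
  # Cox estimate must fall within 3 SE of the truth
  cfg <- sim_config(n_patients = 2000, n_genes = 10, n_snps = 10,
                    clinical_effects = c(venous_infiltration = log(2)),
                    frailty_sd = 0, signature_spec = list(),
                    eqtl_spec = list(n = 0, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 0, effect = 0, on_eqtl_frac = 0),
                    seed = 9L)
  cl <- generate_clinical(cfg)
  sv <- generate_survival(cl, cfg)
  X <- clinical_design(cl)[, "venous_infiltration", drop = FALSE]
  fit <- fit_cox(X, sv$outcome)
  expect_lt(abs(unname(fit$coefficients) - log(2)), 3 * unname(fit$se))
})

test_that("null clinical effects give a calibrated covariate screen", {
  # all effects zero: screening 1000 noise covariates at n=400 must reject
  # at close to the nominal 5% rate
  cfg <- sim_config(n_patients = 400, n_genes = 10, n_snps = 10,
                    clinical_effects = c(venous_infiltration = 0),
                    frailty_sd = 0, signature_spec = list(),
                    eqtl_spec = list(n = 0, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 0, effect = 0, on_eqtl_frac = 0),
                    seed = 10L)
  cl <- generate_clinical(cfg)
  sv <- generate_survival(cl, cfg)
  set.seed(101)
  Z <- matrix(rnorm(400 * 1000), 400,
              dimnames = list(NULL, sprintf("z%04d", 1:1000)))
  p <- suppressWarnings(univariate_screen(Z, sv$outcome))
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("expression noise genes are clean when nuisance is off", {
  cfg <- small_config(seed = 11L,
                      nuisance = list(age_sd = 0, sex_sd = 0,
                                      outlier_rate = 0))
  ch <- generate_cohort(cfg)
  # a gene outside every planted block is mean-0 noise
  g_noise <- ch$expr_normal[nrow(ch$expr_normal), ]
  expect_lt(abs(mean(g_noise)), 3 / sqrt(length(g_noise)))
})

test_that("planted signature genes dominate the within-stratum screen", {
  cfg <- sim_config(n_patients = 200, n_genes = 500, n_snps = 20,
                    signature_spec = list(list(stratum = "good",
                      tissue = "tumor", size = 60, effect = 2.0,
                      rho = 0.3)),
                    eqtl_spec = list(n = 0, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 0, effect = 0, on_eqtl_frac = 0),
                    seed = 12L)
  ch <- generate_cohort(cfg)
  good <- names(ch$truth$stratum)[ch$truth$stratum == "good"]
  o <- ch$dfs[match(good, ch$dfs$patient_id), ]
  p <- suppressWarnings(univariate_screen(t(ch$expr_tumor[, good]), o))
  planted <- ch$truth$signature[[1]]$genes
  expect_lt(median(p[planted]), median(p[setdiff(names(p), planted)]))
})

test_that("genotype dosages follow Hardy-Weinberg at the configured MAF", {
  cfg <- sim_config(n_patients = 2000, n_genes = 20, n_snps = 5,
                    maf_range = c(0.5, 0.5), signature_spec = list(),
                    eqtl_spec = list(n = 0, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 0, effect = 0, on_eqtl_frac = 0),
                    seed = 13L)
  g <- generate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  expect_lt(abs(mean(g$dosage) - 1), 0.03)
  # planted eQTL SNPs sit inside the cis window of their target
  cfg2 <- small_config(seed = 14L)
  g2 <- generate_genotypes(cfg2)
  pos <- g2$snp_pos$bp[match(g2$truth$eqtl$snp, g2$snp_pos$snp)]
  tss <- g2$gene_pos$tss[match(g2$truth$eqtl$gene, g2$gene_pos$gene)]
  expect_true(all(abs(pos - tss) <= cfg2$eqtl_spec$cis_bp))
})

test_that("cohort tables round-trip through the TSV layout", {
  cfg <- sim_config(n_patients = 25, n_genes = 30, n_snps = 20,
                    signature_spec = list(),
                    eqtl_spec = list(n = 3, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 2, effect = 0.4,
                                     on_eqtl_frac = 0.5),
                    seed = 15L)
  ch <- generate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$clinical$patient_id, ch$clinical$patient_id)
  expect_equal(back$survival$time, ch$survival$time, tolerance = 1e-12)
  expect_equal(unname(back$expr_tumor), unname(ch$expr_tumor),
               tolerance = 1e-12)
  expect_equal(unname(back$genotypes$dosage),
               unname(ch$genotypes$dosage))
  expect_equal(back$truth$censoring_realized,
               ch$truth$censoring_realized, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
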