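test_that("BH step-up reproduces the hand-worked example", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.3, 1.0)
  res <- bh_fdr(p, q = 0.05)
  expect_equal(res$threshold, 0.008)
  expect_equal(res$n_discoveries, 2L)
  expect_identical(res$discoveries, p <= 0.008)
  expect_equal(bh_fdr(rep(1, 10), q = 0.1)$n_discoveries, 0L)
  expect_equal(bh_fdr(runif(20), q = 1)$n_discoveries, 20L)
  expect_error(bh_fdr(numeric(0)), class = "schema_error")
})

test_that("BH discoveries agree with p.adjust on random inputs", {
  set.seed(401)
  for (r in 1:5) {
    p <- runif(200)^2
    q <- sample(c(0.05, 0.1, 0.2), 1)
    mine <- bh_fdr(p, q)$discoveries
    ref <- p.adjust(p, method = "BH") <= q
    expect_identical(mine, ref)
  }
})

test_that("cis scan tests exactly the pairs inside the window", {
  set.seed(411)
  n <- 50
  ids <- sprintf("P%03d", 1:n)
  dosage <- matrix(rbinom(3 * n, 2, 0.4), 3, n,
                   dimnames = list(c("s1", "s2", "s3"), ids))
  dosage["s3", ] <- 1  # monomorphic
  snp_pos <- data.frame(snp = c("s1", "s2", "s3"), chrom = "1",
                        bp = c(100000, 5000000, 120000))
  expr <- matrix(rnorm(n), 1, n, dimnames = list("gA", ids))
  gene_pos <- data.frame(gene = "gA", chrom = "1", tss = 150000)
  scan <- cis_eqtl_scan(dosage, snp_pos, expr, gene_pos,
                        window_bp = 1000000)
  # s2 is beyond the window, s3 monomorphic: only s1 is tested
  expect_identical(scan$snp, "s1")
  # the regression p matches lm
  p_ref <- summary(lm(expr[1, ] ~ dosage["s1", ]))$coefficients[2, 4]
  expect_equal(scan$p, p_ref, tolerance = 1e-10)
})

test_that("planted eQTLs reach the study's cis significance level", {
  cfg <- sim_config(n_patients = 300, n_genes = 150, n_snps = 100,
                    signature_spec = list(),
                    eqtl_spec = list(n = 10, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 0, effect = 0, on_eqtl_frac = 0),
                    seed = 421L)
  ch <- generate_cohort(cfg)
  scan <- cis_eqtl_scan(ch$genotypes$dosage, ch$genotypes$snp_pos,
                        ch$expr_normal, ch$genotypes$gene_pos)
  truth <- ch$truth$eqtl
  key <- paste(scan$snp, scan$gene)
  p_pl <- scan$p[match(paste(truth$snp, truth$gene), key)]
  # 1 SD/allele at n=300: essentially every planted pair clears 9E-6
  expect_gte(sum(p_pl < 9e-6), 9L)
})

test_that("null cis p-values are uniform", {
  set.seed(431)
  n <- 300
  ids <- sprintf("P%03d", 1:n)
  M <- 40; G <- 40
  dosage <- matrix(rbinom(M * n, 2, 0.3), M, n,
                   dimnames = list(sprintf("s%02d", 1:M), ids))
  snp_pos <- data.frame(snp = rownames(dosage), chrom = "1",
                        bp = seq(1e5, 4e6, length.out = M))
  expr <- matrix(rnorm(G * n), G, n,
                 dimnames = list(sprintf("g%02d", 1:G), ids))
  gene_pos <- data.frame(gene = rownames(expr), chrom = "1",
                         tss = seq(1e5, 4e6, length.out = G))
  scan <- cis_eqtl_scan(dosage, snp_pos, expr, gene_pos)
  expect_gt(nrow(scan), 500)
  ks <- suppressWarnings(ks.test(scan$p, "punif"))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("cSNP scan applies the adjustment and skip policy", {
  cfg <- sim_config(n_patients = 300, n_genes = 20, n_snps = 60,
                    signature_spec = list(),
                    eqtl_spec = list(n = 0, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 4, effect = 0.8,
                                     on_eqtl_frac = 0),
                    seed = 441L)
  ch <- generate_cohort(cfg)
  dosage <- ch$genotypes$dosage
  dosage[1, ] <- 2  # force one monomorphic SNP
  clin <- clinical_design(ch$clinical)[, c("log_tumor_size", "notn",
                                           "venous_infiltration")]
  cs <- suppressWarnings(
    csnp_scan(dosage, ch$survival, clin, alpha = 0.01))
  expect_false(rownames(dosage)[1] %in% cs$universe)
  expect_equal(length(cs$universe), nrow(dosage) - 1L)
  planted <- setdiff(ch$truth$csnp$snp, rownames(dosage)[1])
  # strong planted per-allele effects are mostly detected
  expect_gte(length(intersect(cs$csnps, planted)),
             length(planted) - 1L)
})

test_that("eSNP/cSNP enrichment handles the degenerate cases", {
  universe <- sprintf("s%03d", 1:100)
  ov0 <- overlap_enrichment(universe[1:10], universe[11:20], universe)
  expect_equal(ov0$fold, 0)
  expect_equal(ov0$p, 1)
  ovfull <- esnp_csnp_enrichment(universe, universe, universe)
  expect_equal(ovfull$fold, 1)
  expect_equal(ovfull$p, 1)
  expect_error(esnp_csnp_enrichment(character(0), universe[1:5], universe),
               class = "undefined_fold_error")
  # fold formula on a known instance: N=1000, |e|=|c|=100, k=25
  uni <- sprintf("u%04d", 1:1000)
  e <- uni[1:100]; cs <- c(uni[1:25], uni[501:575])
  ov <- esnp_csnp_enrichment(e, cs, uni)
  expect_equal(ov$fold, 2.5)
  expect_equal(ov$p,
               phyper(24, 100, 900, 100, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("pseudo-cSNP null is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 120, n_genes = 20, n_snps = 50,
                    signature_spec = list(),
                    eqtl_spec = list(n = 0, effect = 1, cis_bp = 5e4),
                    csnp_spec = list(n = 0, effect = 0, on_eqtl_frac = 0),
                    seed = 451L)
  ch <- generate_cohort(cfg)
  esnps <- rownames(ch$genotypes$dosage)[1:10]
  run <- function() pseudo_csnp_null(ch$genotypes$dosage, ch$survival,
                                     NULL, esnps, alpha = 0.05,
                                     n_perm = 4, seed = 5L)
  n1 <- suppressWarnings(run()); n2 <- suppressWarnings(run())
  expect_identical(n1$null_folds, n2$null_folds)
  expect_identical(n1$null_counts, n2$null_counts)
  expect_true(n1$empirical_p > 0 && n1$empirical_p <= 1)
})
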