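#' Cis-eQTL scan by per-pair linear regression
#'
#' For every gene, each SNP whose position lies within `window_bp` of the
#' gene's transcription start site is tested by simple linear regression of
#' the expression trait on the additive dosage; the two-sided t-test p per
#' pair is returned. Monomorphic SNPs are skipped; genes with no cis SNP
#' are omitted (counted in the `genes_skipped` attribute).
#'
#' @param dosage numeric matrix, SNPs x patients, additive dosages 0/1/2.
#' @param snp_pos data frame with columns `snp`, `chrom`, `bp`.
#' @param expr numeric matrix, genes x patients (same patient order as
#'   `dosage`).
#' @param gene_pos data frame with columns `gene`, `chrom`, `tss`.
#' @param window_bp cis window half-width around the TSS (default 1 Mb).
#' @return Data frame (class `eqtl_scan`) with columns `snp`, `gene`,
#'   `beta`, `p`; attribute `genes_skipped`.
#' @export
cis_eqtl_scan <- function(dosage, snp_pos, expr, gene_pos,
                          window_bp = 1000000L) {
  dosage <- as.matrix(dosage)
  expr <- as.matrix(expr)
  if (ncol(dosage) != ncol(expr))
    ps_stop("dosage and expression patient counts differ", "schema_error")
  if (!all(rownames(dosage) %in% snp_pos$snp))
    ps_stop("SNPs missing from position table", "schema_error")
  if (!all(rownames(expr) %in% gene_pos$gene))
    ps_stop("genes missing from position table", "schema_error")
  n <- ncol(dosage)
  if (n < 10L)
    ps_stop("cis-eQTL scan requires at least 10 patients", "schema_error")
  sp <- snp_pos[match(rownames(dosage), snp_pos$snp), ]
  gp <- gene_pos[match(rownames(expr), gene_pos$gene), ]
  poly <- apply(dosage, 1L, function(x) stats::var(x) > 1e-12)
  res <- vector("list", nrow(expr))
  genes_skipped <- 0L
  for (g in seq_len(nrow(expr))) {
    cis <- which(sp$chrom == gp$chrom[g] &
                   abs(sp$bp - gp$tss[g]) <= window_bp & poly)
    if (length(cis) == 0L) { genes_skipped <- genes_skipped + 1L; next }
    y <- expr[g, ]
    X <- dosage[cis, , drop = FALSE]
    # per-SNP simple regression, vectorized over the cis set
    xc <- X - rowMeans(X)
    yc <- y - mean(y)
    sxx <- rowSums(xc^2)
    sxy <- drop(xc %*% yc)
    beta <- sxy / sxx
    rss <- sum(yc^2) - beta * sxy
    sigma2 <- rss / (n - 2L)
    se <- sqrt(sigma2 / sxx)
    tt <- beta / se
    p <- 2 * stats::pt(-abs(tt), df = n - 2L)
    res[[g]] <- data.frame(snp = rownames(X), gene = rownames(expr)[g],
                           beta = beta, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(snp = character(0), gene = character(0),
                      beta = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  attr(out, "genes_skipped") <- genes_skipped
  class(out) <- c("eqtl_scan", class(out))
  out
}

#' Benjamini-Hochberg step-up false discovery control
#'
#' Returns the largest p(i) with p(i) <= i*q/m (0 if none) and the
#' discovery flags `p <= threshold`, which reproduce the step-up discovery
#' set exactly.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate (default 0.10).
#' @return List: `threshold`, `discoveries` (logical, aligned with input),
#'   `n_discoveries`.
#' @export
bh_fdr <- function(pvalues, q = 0.10) {
  if (length(pvalues) == 0L)
    ps_stop("empty p-value vector", "schema_error")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    ps_stop("p-values must lie in [0, 1]", "schema_error")
  m <- length(pvalues)
  ps <- sort(pvalues)
  ok <- which(ps <= seq_len(m) * q / m)
  threshold <- if (length(ok) == 0L) 0 else ps[max(ok)]
  disc <- pvalues <= threshold & threshold > 0
  list(threshold = threshold, discoveries = disc,
       n_discoveries = sum(disc))
}

#' Extract eSNPs from a cis-eQTL scan at a target FDR
#'
#' Applies [bh_fdr()] over all tested cis pairs; eSNPs are the SNPs
#' significant for at least one gene.
#'
#' @param scan a [cis_eqtl_scan()] result.
#' @param q target FDR (default 0.10).
#' @return List of class `eqtl_result`: significant `pairs`, `esnps`,
#'   the implied `p_threshold` and `q`.
#' @export
esnps_at_fdr <- function(scan, q = 0.10) {
  fdr <- bh_fdr(scan$p, q = q)
  pairs <- scan[fdr$discoveries, , drop = FALSE]
  structure(list(pairs = pairs, esnps = unique(pairs$snp),
                 p_threshold = fdr$threshold, q = q,
                 n_tested = nrow(scan)),
            class = "eqtl_result")
}

#' Outcome-associated SNP (cSNP) scan
#'
#' Per-SNP Cox screen of the additive dosage against the endpoint,
#' conditional on the clinicopathologic covariates (their Cox linear
#' predictor enters as a fixed offset). SNPs with Wald p below `alpha` are
#' the cSNPs; monomorphic SNPs are excluded from the universe.
#'
#' @param dosage numeric matrix, SNPs x patients.
#' @param outcome a [survival_outcome()] aligned with the columns.
#' @param clinical numeric adjustment covariate matrix (patients x q), or
#'   `NULL` for an unadjusted scan.
#' @param alpha significance level (default 0.01).
#' @return List of class `csnp_result`: `csnps`, per-SNP `p` (tested
#'   universe only), `universe` (polymorphic SNP ids), `alpha`.
#' @export
csnp_scan <- function(dosage, outcome, clinical = NULL, alpha = 0.01) {
  dosage <- as.matrix(dosage)
  outcome <- validate_outcome(outcome)
  if (ncol(dosage) != nrow(outcome))
    ps_stop("dosage patient count does not match outcome", "schema_error")
  poly <- apply(dosage, 1L, function(x) stats::var(x) > 1e-12)
  X <- t(dosage[poly, , drop = FALSE])
  p <- suppressWarnings(univariate_screen(X, outcome, adjust = clinical))
  csnps <- names(p)[p < alpha]
  structure(list(csnps = csnps, p = p,
                 universe = rownames(dosage)[poly], alpha = alpha),
            class = "csnp_result")
}

#' eSNP-in-cSNP enrichment
#'
#' Fold enrichment of outcome-associated SNPs among the eSNPs:
#' `(|e n c| / |e|) / (|c| / N)`, with the one-sided hypergeometric
#' upper-tail p over the SNP universe.
#'
#' @param esnps,csnps character vectors of SNP ids.
#' @param snp_universe all SNPs eligible for both scans.
#' @return An `overlap_result` (see [overlap_enrichment()]).
#' @export
esnp_csnp_enrichment <- function(esnps, csnps, snp_universe) {
  if (length(esnps) == 0L)
    ps_stop("empty eSNP set: fold enrichment undefined",
            "undefined_fold_error")
  overlap_enrichment(esnps, csnps, snp_universe)
}

#' Randomized-endpoint pseudo-cSNP null for eSNP enrichment
#'
#' The clinical endpoints (time, event pairs) are permuted jointly across
#' patients, destroying any genotype-outcome link while preserving the
#' censoring pattern, and the adjusted Cox SNP scan is repeated. SNPs
#' passing the scan on permuted endpoints are pseudo-cSNPs arising purely
#' from type-I error; the eSNP enrichment fold against them should center
#' at 1. The fraction of null folds at or above the observed fold gives an
#' empirical enrichment p-value.
#'
#' @param dosage numeric matrix, SNPs x patients.
#' @param outcome a [survival_outcome()].
#' @param clinical adjustment covariate matrix or `NULL`.
#' @param esnps character vector of eSNP ids.
#' @param alpha cSNP scan level (default 0.01).
#' @param n_perm number of endpoint permutations (default 20).
#' @param seed RNG seed for the permutations.
#' @return List of class `pseudo_csnp_null`: `null_folds`, `null_counts`,
#'   `observed_fold`, `observed_count`, `empirical_p`.
#' @export
pseudo_csnp_null <- function(dosage, outcome, clinical, esnps,
                             alpha = 0.01, n_perm = 20L, seed = 1L) {
  if (n_perm < 1L)
    ps_stop("n_perm must be at least 1", "config_error")
  outcome <- validate_outcome(outcome)
  obs <- csnp_scan(dosage, outcome, clinical, alpha = alpha)
  obs_enr <- if (length(obs$csnps) == 0L) NULL else
    esnp_csnp_enrichment(esnps, obs$csnps, obs$universe)
  observed_fold <- if (is.null(obs_enr)) 0 else obs_enr$fold
  n <- nrow(outcome)
  null_folds <- numeric(n_perm)
  null_counts <- integer(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      o_b <- outcome
      o_b$time <- outcome$time[perm]
      o_b$event <- outcome$event[perm]
      scan_b <- csnp_scan(dosage, o_b, clinical, alpha = alpha)
      null_counts[b] <- length(scan_b$csnps)
      null_folds[b] <- if (length(scan_b$csnps) == 0L) 0 else
        suppressWarnings(
          esnp_csnp_enrichment(esnps, scan_b$csnps, scan_b$universe)$fold)
    }
  })
  structure(list(null_folds = null_folds, null_counts = null_counts,
                 observed_fold = observed_fold,
                 observed_count = length(obs$csnps),
                 empirical_p = (sum(null_folds >= observed_fold) + 1) /
                   (n_perm + 1),
                 alpha = alpha, n_perm = n_perm),
            class = "pseudo_csnp_null")
}
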