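#' Write a cohort to the standard tab-separated layout
#'
#' Emits `clinical.tsv`, `survival.tsv`, `dfs.tsv`, `expr_tumor.tsv`,
#' `expr_normal.tsv`, `genotypes.tsv`, `snp_pos.tsv`, `gene_pos.tsv` and
#' `truth.json` into `dir`. All tables carry a header row and share the
#' same patient column order.
#'
#' @param cohort a [generate_cohort()] result (or a compatible list).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, file, rn = FALSE) {
    if (rn) x <- cbind(data.frame(id = rownames(x)), as.data.frame(x))
    write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(cohort$clinical, "clinical.tsv")
  tsv(as.data.frame(cohort$survival), "survival.tsv")
  tsv(as.data.frame(cohort$dfs), "dfs.tsv")
  tsv(cohort$expr_tumor, "expr_tumor.tsv", rn = TRUE)
  tsv(cohort$expr_normal, "expr_normal.tsv", rn = TRUE)
  tsv(cohort$genotypes$dosage, "genotypes.tsv", rn = TRUE)
  tsv(cohort$genotypes$snp_pos, "snp_pos.tsv")
  tsv(cohort$genotypes$gene_pos, "gene_pos.tsv")
  truth <- cohort$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a cohort from the standard tab-separated layout
#'
#' Loads the tables written by [write_cohort()] and validates the schema:
#' required columns, numeric cells, and patient-id alignment across
#' clinical, outcome, expression and genotype tables. Misaligned ids are
#' reported explicitly.
#'
#' @param dir directory holding the cohort tables.
#' @return List with the same components as [generate_cohort()] (minus
#'   config; `truth` only if `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  need <- c("clinical.tsv", "survival.tsv", "dfs.tsv", "expr_tumor.tsv",
            "expr_normal.tsv", "genotypes.tsv", "snp_pos.tsv",
            "gene_pos.tsv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files))
    ps_stop(paste0("missing cohort files: ",
                   paste(missing_files, collapse = ", ")), "schema_error")
  clinical <- read.delim(file.path(dir, "clinical.tsv"),
                         stringsAsFactors = FALSE)
  outc <- function(f) {
    df <- read.delim(file.path(dir, f), stringsAsFactors = FALSE)
    survival_outcome(df$patient_id, df$time, df$event)
  }
  surv <- outc("survival.tsv")
  dfs <- outc("dfs.tsv")
  expr_tumor <- read_matrix_tsv(file.path(dir, "expr_tumor.tsv"))
  expr_normal <- read_matrix_tsv(file.path(dir, "expr_normal.tsv"))
  dosage <- read_matrix_tsv(file.path(dir, "genotypes.tsv"))
  snp_pos <- read.delim(file.path(dir, "snp_pos.tsv"),
                        stringsAsFactors = FALSE)
  gene_pos <- read.delim(file.path(dir, "gene_pos.tsv"),
                         stringsAsFactors = FALSE)

  ids <- clinical$patient_id
  check_ids <- function(got, what) {
    extra <- setdiff(got, ids)
    if (length(extra))
      ps_stop(paste0(what, " has patients absent from clinical: ",
                     paste(extra, collapse = ", ")), "schema_error")
    miss <- setdiff(ids, got)
    if (length(miss))
      ps_stop(paste0(what, " is missing patients: ",
                     paste(miss, collapse = ", ")), "schema_error")
  }
  check_ids(surv$patient_id, "survival.tsv")
  check_ids(dfs$patient_id, "dfs.tsv")
  check_ids(colnames(expr_tumor), "expr_tumor.tsv")
  check_ids(colnames(expr_normal), "expr_normal.tsv")
  check_ids(colnames(dosage), "genotypes.tsv")
  if (anyNA(expr_tumor) || anyNA(expr_normal) || anyNA(dosage))
    ps_stop("non-numeric or missing cells in matrix tables",
            "schema_error")

  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(clinical = clinical, survival = surv, dfs = dfs,
                 expr_tumor = expr_tumor, expr_normal = expr_normal,
                 genotypes = list(dosage = dosage, snp_pos = snp_pos,
                                  gene_pos = gene_pos),
                 truth = truth),
            class = "synthetic_cohort")
}

#' Run the full two-stage analysis end to end
#'
#' Simulates (or accepts) a cohort and runs every stage: robust age/sex
#' residualization of both expression matrices, the two-stage stratified
#' predictor per requested endpoint and tissue, signature derivation with
#' overlap enrichment against supplied gene lists (the planted signature
#' genes for a synthetic cohort), and the cis-eQTL / cSNP enrichment
#' analyses with the randomized-endpoint null. Returns a machine-readable
#' summary and optionally writes `summary.json`.
#'
#' @param config a [sim_config()]; ignored when `cohort` is given.
#' @param cohort optional pre-built cohort (e.g. from [read_cohort()]);
#'   skips simulation.
#' @param endpoints endpoints to analyze (`"survival"`, `"dfs"`).
#' @param tissues stage-2 tissues to run (subset of
#'   `c("normal", "tumor", "dual")`).
#' @param K,m stage-2 selection size and PC count.
#' @param signature_cutoff p cutoff for signature derivation.
#' @param fdr_q FDR level of the eQTL analysis.
#' @param csnp_alpha level of the cSNP scan.
#' @param n_perm pseudo-cSNP permutations.
#' @param residualize apply [robust_residualize()] before stage 2.
#' @param out optional output directory for `summary.json`.
#' @return Nested summary list (also written as JSON when `out` is given).
#' @export
run_all <- function(config = sim_config(), cohort = NULL,
                    endpoints = c("survival", "dfs"),
                    tissues = "normal", K = 100L, m = 6L,
                    signature_cutoff = 5e-4, fdr_q = 0.10,
                    csnp_alpha = 0.01, n_perm = 20L,
                    residualize = TRUE, out = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  expr <- list(tumor = cohort$expr_tumor, normal = cohort$expr_normal)
  if (residualize)
    expr <- lapply(expr, robust_residualize, clinical = cohort$clinical)

  summary <- list(seed = if (is.null(cohort$config)) NA else
                    cohort$config$seed,
                  n_patients = nrow(cohort$clinical),
                  censoring_realized =
                    mean(cohort$survival$event == 0))

  for (ep in endpoints) {
    outcome <- if (ep == "survival") cohort$survival else cohort$dfs
    ep_sum <- list()
    for (ti in tissues) {
      rep <- suppressWarnings(
        stratified_pipeline(cohort$clinical, outcome, expr, tissue = ti,
                            K = K, m = m))
      ep_sum[[ti]] <- list(
        clinical_logrank_p = rep$clinical$logrank$p,
        strata = lapply(rep$strata, function(s)
          list(n = nrow(s$assignment), logrank_p = s$logrank$p)))
    }
    # tier signature + overlap against planted truth (synthetic mode) --
    # external lists slot in the same way
    sig_tissue <- if ("normal" %in% tissues) "normal" else tissues[1]
    sig <- suppressWarnings(
      derive_signature(expr[[sig_tissue]], outcome,
                       p_cutoff = signature_cutoff))
    ep_sum$signature_size <- length(sig$genes)
    if (!is.null(cohort$truth) && length(cohort$truth$signature)) {
      planted <- unique(unlist(lapply(cohort$truth$signature, function(s)
        if (s$tissue == sig_tissue) s$genes else character(0))))
      if (length(planted)) {
        ov <- suppressWarnings(
          overlap_enrichment(sig$genes, planted, sig$universe))
        ep_sum$signature_overlap <- list(overlap = ov$overlap,
                                         fold = ov$fold, p = ov$p)
      }
    }
    summary[[ep]] <- ep_sum
  }

  # genetics: eQTL scan in adjacent-normal tissue, cSNP scan per survival
  geno <- cohort$genotypes
  scan <- cis_eqtl_scan(geno$dosage, geno$snp_pos, expr$normal,
                        geno$gene_pos)
  eq <- esnps_at_fdr(scan, q = fdr_q)
  clin_X <- clinical_design(cohort$clinical)[, c(
    "log_tumor_size", "notn", "log_afp", "albu", "venous_infiltration",
    "ptnm"), drop = FALSE]
  cs <- csnp_scan(geno$dosage, cohort$survival, clin_X,
                  alpha = csnp_alpha)
  enr <- if (length(eq$esnps)) suppressWarnings(
    esnp_csnp_enrichment(eq$esnps, cs$csnps, cs$universe)) else NULL
  null <- if (length(eq$esnps)) pseudo_csnp_null(
    geno$dosage, cohort$survival, clin_X, eq$esnps, alpha = csnp_alpha,
    n_perm = n_perm,
    seed = (if (is.null(cohort$config)) 1L else cohort$config$seed) + 11L)
    else NULL
  summary$genetics <- list(
    n_eqtl_pairs = nrow(eq$pairs), n_esnps = length(eq$esnps),
    eqtl_p_threshold = eq$p_threshold, n_csnps = length(cs$csnps),
    esnp_csnp_fold = if (is.null(enr)) NA else enr$fold,
    esnp_csnp_p = if (is.null(enr)) NA else enr$p,
    pseudo_csnp_mean_count = if (is.null(null)) NA else
      mean(null$null_counts),
    pseudo_csnp_mean_fold = if (is.null(null)) NA else
      mean(null$null_folds),
    pseudo_empirical_p = if (is.null(null)) NA else null$empirical_p)

  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  summary
}
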