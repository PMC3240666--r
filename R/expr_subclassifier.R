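#' Select the top-K genes by univariate Cox screening
#'
#' Ranks genes by the two-sided Wald p of a per-gene univariate Cox model
#' (optionally conditional on adjustment covariates) and returns the K
#' smallest. Ties are broken by ascending gene id so selection is
#' deterministic; degenerate genes are ineligible. If fewer than K eligible
#' genes exist, K is lowered with a warning.
#'
#' @param expr numeric matrix, genes in rows, patients in columns.
#' @param outcome a [survival_outcome()] aligned with the columns.
#' @param K number of genes to select (default 100).
#' @param adjust optional adjustment covariate matrix (patients x q).
#' @return Character vector of selected gene ids.
#' @export
select_top_genes <- function(expr, outcome, K = 100L, adjust = NULL) {
  expr <- as.matrix(expr)
  det <- suppressWarnings(
    univariate_screen(t(expr), outcome, adjust = adjust, details = TRUE))
  elig <- det[!det$degenerate, , drop = FALSE]
  if (nrow(elig) < K) {
    ps_warn(sprintf("only %d eligible genes; K lowered from %d",
                    nrow(elig), K), "k_lowered_warning")
    K <- nrow(elig)
  }
  elig <- elig[order(elig$p, elig$feature), , drop = FALSE]
  elig$feature[seq_len(K)]
}

#' Fit a principal-component basis on training expression
#'
#' Covariance PCA (genes centered by training means, not rescaled) of a
#' patients x genes matrix; loadings are the top-m eigenvectors of the gene
#' covariance, with each loading's sign fixed so its largest-magnitude
#' coordinate is positive (a reproducibility convention). If m is at least
#' the matrix rank, m is reduced to the rank with a warning.
#'
#' @param x numeric matrix, training patients in rows, genes in columns.
#' @param m number of components to retain (default 6).
#' @return Object of class `pca_model`: gene ids, training means,
#'   orthonormal `loadings` (genes x m), explained-variance fractions for
#'   the retained components (`explained`) and the full spectrum
#'   (`explained_all`).
#' @export
pca_fit <- function(x, m = 6L) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("g", seq_len(ncol(X)))
  means <- colMeans(X)
  Xc <- sweep(X, 2L, means, "-")
  sv <- svd(Xc)
  d2 <- sv$d^2
  tot <- sum(d2)
  rank <- if (tot <= 0) 0L else sum(sv$d > sv$d[1] * 1e-8)
  if (m > rank) {
    ps_warn(sprintf("m reduced from %d to matrix rank %d", m, rank),
            "m_reduced_warning")
    m <- rank
  }
  expl_all <- if (tot <= 0) rep(0, length(d2)) else d2 / tot
  load <- sv$v[, seq_len(m), drop = FALSE]
  # sign convention: largest-|entry| coordinate of each loading positive
  for (j in seq_len(m)) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(X)
  if (m > 0) colnames(load) <- paste0("PC", seq_len(m))
  structure(list(genes = colnames(X), means = means, loadings = load,
                 explained = expl_all[seq_len(m)],
                 explained_all = expl_all, m = m),
            class = "pca_model")
}

#' Project samples onto a fitted principal-component basis
#'
#' Scores are `loadings' (x - training_means)`; projecting a training
#' sample reproduces its training scores exactly.
#'
#' @param model a [pca_fit()] result.
#' @param sample named numeric vector (one sample) or matrix with samples
#'   in rows and genes in columns; must cover the model's genes.
#' @return Score matrix, samples x m.
#' @export
pca_project <- function(model, sample) {
  if (is.matrix(sample) || is.data.frame(sample)) {
    S <- as.matrix(sample)
  } else {
    S <- matrix(sample, nrow = 1L, dimnames = list(NULL, names(sample)))
  }
  if (is.null(colnames(S)) || !all(model$genes %in% colnames(S)))
    ps_stop("sample does not cover the model's gene subset", "schema_error")
  S <- S[, model$genes, drop = FALSE]
  sweep(S, 2L, model$means, "-") %*% model$loadings
}

# Fit the per-fold Cox model on PC scores (+ optional clinical columns)
# with the degenerate-fold fallback ladder: m PCs, then m-1, ..., 1; NULL
# if nothing converges (caller uses the h = 0 sentinel).
fit_fold_cox <- function(scores, clin, outcome) {
  m_full <- ncol(scores)
  for (mm in rev(seq_len(m_full))) {
    covs <- scores[, seq_len(mm), drop = FALSE]
    if (!is.null(clin)) covs <- cbind(covs, clin)
    fit <- tryCatch(suppressWarnings(fit_cox(covs, outcome)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged)
      return(list(fit = fit, m_used = mm))
  }
  NULL
}

# core of one leave-one-out iteration, shared by the nested and leaky
# variants: train screening/PCA/Cox on `tr`, return held-out h and audit
fold_predict <- function(Xall, outcome, i, genes, m, clin) {
  tr <- setdiff(seq_len(nrow(Xall)), i)
  otr <- outcome[tr, , drop = FALSE]
  pca <- suppressWarnings(pca_fit(Xall[tr, genes, drop = FALSE], m))
  if (pca$m == 0L) return(NULL)
  scores_tr <- pca_project(pca, Xall[tr, genes, drop = FALSE])
  clin_tr <- if (is.null(clin)) NULL else clin[tr, , drop = FALSE]
  fc <- fit_fold_cox(scores_tr, clin_tr, otr)
  if (is.null(fc)) return(NULL)
  s_i <- pca_project(pca, Xall[i, genes, drop = FALSE])
  row_i <- s_i[, seq_len(fc$m_used), drop = FALSE]
  if (!is.null(clin)) row_i <- cbind(row_i, clin[i, , drop = FALSE])
  list(h = unname(linear_predictor(fc$fit, row_i)),
       pca = pca, fit = fc$fit, m_used = fc$m_used)
}

#' Nested leave-one-out gene-expression predictor
#'
#' For each patient, the full training recipe is redone on the remaining
#' patients: univariate Cox gene screen (conditional on the clinical
#' covariates in `expr_plus_clinical` mode), selection of the K
#' smallest-p genes, covariance PCA, a Cox model on the top m component
#' scores (plus the clinical covariates in combined mode), and projection
#' of the held-out patient to obtain their relative hazard `h`. Because
#' screening and the PC basis are re-derived inside every fold, the
#' returned `h` carries no feature-selection optimism. Folds whose Cox fit
#' does not converge fall back to fewer components and, as a last resort,
#' to the `h = 0` sentinel so every patient stays labeled.
#'
#' @param expr numeric matrix, genes in rows, patients in columns.
#' @param outcome a [survival_outcome()] for the same patients.
#' @param K genes selected per fold (default 100).
#' @param m principal components retained per fold (default 6).
#' @param mode `"expr_only"` or `"expr_plus_clinical"` (clinical covariates
#'   enter both the screen, as an offset, and the prediction model).
#' @param clinical numeric covariate matrix (patients x q), required in
#'   combined mode.
#' @param keep_folds if `TRUE`, per-fold audit records (held-out id,
#'   selected genes, PCA model, Cox fit, h) are returned.
#' @return Named numeric vector `h`; with `keep_folds`, attribute
#'   `"folds"` holds the audit records.
#' @export
loo_expression_predictor <- function(expr, outcome, K = 100L, m = 6L,
                                     mode = c("expr_only",
                                              "expr_plus_clinical"),
                                     clinical = NULL, keep_folds = TRUE) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  outcome <- validate_outcome(outcome)
  if (is.null(colnames(expr)) ||
      !all(outcome$patient_id %in% colnames(expr)))
    ps_stop("expression columns do not cover outcome patients",
            "schema_error")
  Xall <- t(expr[, outcome$patient_id, drop = FALSE])
  n <- nrow(Xall)
  if (n < 20L)
    ps_stop("leave-one-out requires at least 20 patients", "schema_error")
  clin <- NULL
  if (mode == "expr_plus_clinical") {
    if (is.null(clinical))
      ps_stop("combined mode requires clinical covariates", "schema_error")
    clin <- as_cov_matrix(clinical)
    if (nrow(clin) != n)
      ps_stop("clinical rows do not match outcome rows", "schema_error")
  }
  h <- numeric(n)
  folds <- if (keep_folds) vector("list", n) else NULL
  n_sentinel <- 0L
  gene_ids <- colnames(Xall)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    otr <- outcome[tr, , drop = FALSE]
    adj <- if (is.null(clin)) NULL else clin[tr, , drop = FALSE]
    p <- suppressWarnings(
      univariate_screen(Xall[tr, , drop = FALSE], otr, adjust = adj))
    ord <- order(p, gene_ids)
    genes <- gene_ids[ord[seq_len(min(K, length(ord)))]]
    fp <- fold_predict(Xall, outcome, i, genes, m, clin)
    if (is.null(fp)) {
      h[i] <- 0
      n_sentinel <- n_sentinel + 1L
    } else {
      h[i] <- fp$h
    }
    if (keep_folds)
      folds[[i]] <- list(held_out = outcome$patient_id[i], genes = genes,
                         pca = fp$pca, cox = fp$fit,
                         m_used = if (is.null(fp)) 0L else fp$m_used,
                         h = h[i])
  }
  if (n_sentinel > 0L)
    ps_warn(sprintf("%d fold(s) fell back to the h = 0 sentinel",
                    n_sentinel), "fold_sentinel_warning")
  names(h) <- outcome$patient_id
  if (keep_folds) attr(h, "folds") <- folds
  h
}

# Deliberately leaky variant: the gene screen and top-K selection are done
# ONCE on all n patients, and only the PCA/Cox stage is cross-validated.
# Kept unexported; it exists to demonstrate (in calibration studies) the
# selection-bias inflation that the nested procedure avoids.
loo_expression_predictor_leaky <- function(expr, outcome, K = 100L, m = 6L) {
  expr <- as.matrix(expr)
  outcome <- validate_outcome(outcome)
  Xall <- t(expr[, outcome$patient_id, drop = FALSE])
  n <- nrow(Xall)
  p <- suppressWarnings(univariate_screen(Xall, outcome))
  ord <- order(p, colnames(Xall))
  genes <- colnames(Xall)[ord[seq_len(min(K, length(ord)))]]
  h <- numeric(n)
  for (i in seq_len(n)) {
    fp <- fold_predict(Xall, outcome, i, genes, m, NULL)
    h[i] <- if (is.null(fp)) 0 else fp$h
  }
  names(h) <- outcome$patient_id
  h
}

#' Dual-tissue nested leave-one-out predictor
#'
#' As [loo_expression_predictor()], but the screen / top-K / PCA stage is
#' run independently per tissue inside each fold, and the fold's Cox model
#' receives both tissues' component scores (2m regressors, e.g. 12 for
#' m = 6), plus clinical covariates when supplied.
#'
#' @param expr_tumor,expr_normal genes x patients matrices; patient
#'   intersection (with `outcome`) must be at least 20.
#' @param outcome a [survival_outcome()].
#' @param K,m per-tissue selection size and component count.
#' @param clinical optional clinical covariate matrix (rows aligned with
#'   `outcome`); enters screening offsets and the fold Cox model.
#' @return Named numeric vector `h` over the common patients.
#' @export
dual_tissue_predictor <- function(expr_tumor, expr_normal, outcome,
                                  K = 100L, m = 6L, clinical = NULL) {
  outcome <- validate_outcome(outcome)
  common <- intersect(intersect(colnames(expr_tumor),
                                colnames(expr_normal)),
                      outcome$patient_id)
  if (length(common) < 20L)
    ps_stop("fewer than 20 patients common to both tissues",
            "schema_error")
  keep <- match(common, outcome$patient_id)
  outcome <- outcome[keep, , drop = FALSE]
  Xt <- t(as.matrix(expr_tumor)[, common, drop = FALSE])
  Xn <- t(as.matrix(expr_normal)[, common, drop = FALSE])
  clin <- NULL
  if (!is.null(clinical)) {
    clin <- as_cov_matrix(clinical)[keep, , drop = FALSE]
  }
  n <- length(common)
  h <- numeric(n)
  n_sentinel <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    otr <- outcome[tr, , drop = FALSE]
    adj <- if (is.null(clin)) NULL else clin[tr, , drop = FALSE]
    tissue_parts <- lapply(list(tumor = Xt, normal = Xn), function(X) {
      p <- suppressWarnings(
        univariate_screen(X[tr, , drop = FALSE], otr, adjust = adj))
      ord <- order(p, colnames(X))
      genes <- colnames(X)[ord[seq_len(min(K, length(ord)))]]
      pca <- suppressWarnings(pca_fit(X[tr, genes, drop = FALSE], m))
      if (pca$m == 0L) return(NULL)
      list(scores_tr = pca_project(pca, X[tr, genes, drop = FALSE]),
           score_i = pca_project(pca, X[i, genes, drop = FALSE]))
    })
    if (any(vapply(tissue_parts, is.null, logical(1)))) {
      h[i] <- 0; n_sentinel <- n_sentinel + 1L; next
    }
    lab <- function(s, tag) {
      colnames(s) <- paste0(colnames(s), "_", tag); s
    }
    scores_tr <- cbind(lab(tissue_parts$tumor$scores_tr, "tumor"),
                       lab(tissue_parts$normal$scores_tr, "normal"))
    row_i <- cbind(lab(tissue_parts$tumor$score_i, "tumor"),
                   lab(tissue_parts$normal$score_i, "normal"))
    clin_tr <- if (is.null(clin)) NULL else clin[tr, , drop = FALSE]
    fc <- fit_fold_cox(scores_tr, clin_tr, otr)
    if (is.null(fc)) { h[i] <- 0; n_sentinel <- n_sentinel + 1L; next }
    keep_cols <- fc$fit$names
    full_i <- if (is.null(clin)) row_i else
      cbind(row_i, clin[i, , drop = FALSE])
    h[i] <- unname(linear_predictor(fc$fit,
                                    full_i[, keep_cols, drop = FALSE]))
  }
  if (n_sentinel > 0L)
    ps_warn(sprintf("%d fold(s) fell back to the h = 0 sentinel",
                    n_sentinel), "fold_sentinel_warning")
  names(h) <- common
  h
}

#' Full two-stage stratified prognosis pipeline
#'
#' Stage 1: leave-one-out clinical linear predictor over the candidate
#' clinicopathologic parameters, median dichotomization into good/poor
#' prognosis groups, and log-rank evaluation of the split. Stage 2: within
#' each stratum independently, the nested leave-one-out expression
#' predictor on the requested tissue(s), a median sub-split of the
#' within-stratum `h`, and its log-rank evaluation. The report also
#' carries the four-way classification (clinical stratum x expression
#' sub-group).
#'
#' @param clinical clinical table (see [generate_clinical()] for the
#'   expected columns).
#' @param outcome a [survival_outcome()] for one endpoint.
#' @param expr named list with elements `tumor` and/or `normal` (genes x
#'   patients matrices).
#' @param tissue `"normal"`, `"tumor"` or `"dual"`.
#' @param K,m stage-2 selection size and component count.
#' @param mode stage-2 mode passed to [loo_expression_predictor()].
#' @param alpha stage-1 univariate selection threshold.
#' @param candidates candidate parameter columns of [clinical_design()];
#'   defaults to the recorded clinicopathologic parameters (age and sex are
#'   expression-adjustment covariates, not candidates).
#' @param min_stratum strata smaller than this are skipped with a warning.
#' @return List of class `stratified_report`: `clinical` (h, assignment,
#'   log-rank, KM), `strata` (per-stratum h, assignment, log-rank, KM) and
#'   `four_way` (patient, clinical label, expression label).
#' @export
stratified_pipeline <- function(clinical, outcome, expr,
                                tissue = c("normal", "tumor", "dual"),
                                K = 100L, m = 6L,
                                mode = c("expr_only", "expr_plus_clinical"),
                                alpha = 0.05,
                                candidates = c("log_tumor_size", "notn",
                                               "log_afp", "albu",
                                               "venous_infiltration",
                                               "ptnm", "ajcc"),
                                min_stratum = 20L) {
  tissue <- match.arg(tissue)
  mode <- match.arg(mode)
  outcome <- validate_outcome(outcome)
  X <- clinical_design(clinical)
  idx <- match(outcome$patient_id, clinical$patient_id)
  if (anyNA(idx))
    ps_stop("outcome patients missing from clinical table", "schema_error")
  X <- X[idx, , drop = FALSE]
  h_clin <- loo_clinical_predictor(X[, candidates, drop = FALSE], outcome,
                                   alpha = alpha)
  assign_clin <- dichotomize(h_clin)
  eval_clin <- evaluate_split(assign_clin, outcome)

  strata <- list()
  four_way <- data.frame(patient_id = assign_clin$patient_id,
                         clinical = assign_clin$label,
                         expression = NA_character_,
                         stringsAsFactors = FALSE)
  for (lab in c("good", "poor")) {
    ids <- assign_clin$patient_id[assign_clin$label == lab]
    if (length(ids) < min_stratum) {
      ps_warn(sprintf("stratum '%s' below minimum size (%d); skipped",
                      lab, length(ids)), "stratum_skipped_warning")
      next
    }
    o_s <- outcome[match(ids, outcome$patient_id), , drop = FALSE]
    clin_s <- if (mode == "expr_plus_clinical")
      X[match(ids, outcome$patient_id), candidates, drop = FALSE] else NULL
    h_s <- if (tissue == "dual") {
      dual_tissue_predictor(expr$tumor, expr$normal, o_s, K = K, m = m,
                            clinical = clin_s)
    } else {
      loo_expression_predictor(expr[[tissue]][, ids, drop = FALSE], o_s,
                               K = K, m = m, mode = mode,
                               clinical = clin_s, keep_folds = FALSE)
    }
    sub <- tryCatch(dichotomize(h_s), error = function(e) NULL)
    if (is.null(sub)) {
      ps_warn(sprintf("stratum '%s' sub-split degenerate; skipped", lab),
              "stratum_skipped_warning")
      next
    }
    o_sub <- o_s[match(sub$patient_id, o_s$patient_id), , drop = FALSE]
    strata[[lab]] <- list(h = h_s, assignment = sub,
                          logrank = log_rank_test(sub$label, o_sub),
                          km = km_estimate(o_sub, sub$label))
    four_way$expression[match(sub$patient_id, four_way$patient_id)] <-
      sub$label
  }
  structure(list(clinical = list(h = h_clin, assignment = assign_clin,
                                 logrank = eval_clin$logrank,
                                 km = eval_clin$km),
                 strata = strata, four_way = four_way,
                 params = list(tissue = tissue, K = K, m = m, mode = mode,
                               alpha = alpha, candidates = candidates)),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("Two-stage stratified prognosis report (tissue: ",
      x$params$tissue, ", K = ", x$params$K, ", m = ", x$params$m, ")\n",
      sep = "")
  cat(sprintf("  clinical split: log-rank p = %.3g\n", x$clinical$logrank$p))
  for (lab in names(x$strata))
    cat(sprintf("  %s stratum sub-split: log-rank p = %.3g (n = %d)\n",
                lab, x$strata[[lab]]$logrank$p,
                nrow(x$strata[[lab]]$assignment)))
  invisible(x)
}
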