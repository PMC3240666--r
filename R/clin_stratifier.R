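#' Select significant clinicopathologic parameters
#'
#' Univariate Cox screen over the candidate covariate columns; parameters
#' with two-sided Wald p below `alpha` are returned in input order.
#'
#' @param covariates numeric matrix, patients x candidate parameters.
#' @param outcome a [survival_outcome()] aligned with the rows.
#' @param alpha selection threshold (two-sided), default 0.05.
#' @return Character vector of selected column names.
#' @export
select_clinical_params <- function(covariates, outcome, alpha = 0.05) {
  X <- as_cov_matrix(covariates)
  if (ncol(X) < 1L)
    ps_stop("no candidate parameters", "schema_error")
  p <- suppressWarnings(univariate_screen(X, outcome))
  sel <- colnames(X)[p < alpha]
  if (length(sel) == 0L)
    ps_stop("no clinicopathologic parameter reached significance",
            "empty_selection_error")
  sel
}

#' Leave-one-out clinical linear predictor
#'
#' For each patient, univariate parameter selection and the multivariate
#' Cox fit are redone on the remaining patients, and the held-out patient's
#' centered linear predictor is recorded. No statistic of fold i ever uses
#' patient i, so the resulting `h` is free of resubstitution optimism.
#' Folds where no parameter reaches significance contribute `h = 0` (null
#' model) and are flagged with a warning.
#'
#' @param covariates numeric matrix of candidate parameters (use
#'   [clinical_design()] columns for a standard clinical table).
#' @param outcome a [survival_outcome()] aligned with the rows.
#' @param alpha univariate selection threshold per fold.
#' @return Named numeric vector `h` (one per patient) with attribute
#'   `"selected"`: the per-fold selected parameter lists.
#' @export
loo_clinical_predictor <- function(covariates, outcome, alpha = 0.05) {
  X <- as_cov_matrix(covariates)
  outcome <- validate_outcome(outcome)
  n <- nrow(X)
  if (n != nrow(outcome))
    ps_stop("covariate rows do not match outcome rows", "schema_error")
  if (n < 20L)
    ps_stop("leave-one-out requires at least 20 patients", "schema_error")
  h <- numeric(n)
  selected <- vector("list", n)
  n_empty <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Xtr <- X[tr, , drop = FALSE]
    otr <- outcome[tr, , drop = FALSE]
    p <- suppressWarnings(univariate_screen(Xtr, otr))
    sel <- colnames(X)[p < alpha]
    selected[[i]] <- sel
    if (length(sel) == 0L) {
      n_empty <- n_empty + 1L
      h[i] <- 0
      next
    }
    fit <- fit_cox(Xtr[, sel, drop = FALSE], otr)
    h[i] <- linear_predictor(fit, X[i, sel, drop = FALSE])
  }
  if (n_empty > 0L)
    ps_warn(sprintf("%d fold(s) with empty parameter selection; h = 0 used",
                    n_empty), "empty_fold_warning")
  names(h) <- outcome$patient_id
  attr(h, "selected") <- selected
  h
}

#' Dichotomize patients on a linear predictor
#'
#' Splits patients at the median of `h` into good (low relative hazard) and
#' poor (high relative hazard) prognosis groups; patients tied with the
#' threshold are assigned to the good group, so group sizes differ by at
#' most the number of ties at the median.
#'
#' @param h named numeric linear predictor (names = patient ids).
#' @param rule dichotomization rule; only `"median"` is implemented.
#' @return A `data.frame` of class `stratum_assignment` with columns
#'   `patient_id`, `h`, `label` and attribute `"threshold"`.
#' @export
dichotomize <- function(h, rule = "median") {
  if (!identical(rule, "median"))
    ps_stop("only the median rule is implemented", "config_error")
  if (!all(is.finite(h)))
    ps_stop("linear predictor contains non-finite values", "schema_error")
  if (length(unique(h)) == 1L)
    ps_stop("all linear-predictor values identical; split degenerate",
            "degenerate_split_error")
  thr <- median(h)
  lab <- ifelse(h <= thr, "good", "poor")
  out <- data.frame(patient_id = if (is.null(names(h)))
                      as.character(seq_along(h)) else names(h),
                    h = as.numeric(h), label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  class(out) <- c("stratum_assignment", class(out))
  out
}

#' Evaluate a prognosis split by log-rank test and Kaplan-Meier curves
#'
#' @param assignment a [dichotomize()] result.
#' @param outcome a [survival_outcome()] covering the assigned patients.
#' @return List with `logrank` (a `logrank_result`) and `km` (a
#'   `km_curve`).
#' @export
evaluate_split <- function(assignment, outcome) {
  outcome <- validate_outcome(outcome)
  idx <- match(assignment$patient_id, outcome$patient_id)
  if (anyNA(idx))
    ps_stop("assignment contains patients missing from outcome",
            "schema_error")
  o <- outcome[idx, , drop = FALSE]
  list(logrank = log_rank_test(assignment$label, o),
       km = km_estimate(o, assignment$label))
}
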