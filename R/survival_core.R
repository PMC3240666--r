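#' Construct a survival outcome table
#'
#' A survival outcome is the per-patient follow-up time in months together
#' with the event indicator for one endpoint (overall survival or
#' disease-free survival).
#'
#' @param patient_id character vector of unique patient identifiers.
#' @param time positive follow-up times (months).
#' @param event integer 0/1; 1 = failure (death or recurrence), 0 = censored.
#' @return A `data.frame` with columns `patient_id`, `time`, `event` of
#'   class `survival_outcome`.
#' @export
survival_outcome <- function(patient_id, time, event) {
  out <- data.frame(patient_id = as.character(patient_id),
                    time = as.numeric(time),
                    event = as.integer(event),
                    stringsAsFactors = FALSE)
  validate_outcome(out)
}

validate_outcome <- function(outcome) {
  if (!all(c("patient_id", "time", "event") %in% names(outcome)))
    ps_stop("outcome must have columns patient_id, time, event",
            "schema_error")
  if (anyDuplicated(outcome$patient_id))
    ps_stop("duplicated patient ids in outcome", "schema_error")
  if (!all(is.finite(outcome$time)) || any(outcome$time <= 0))
    ps_stop("follow-up times must be finite and positive", "schema_error")
  if (!all(outcome$event %in% c(0L, 1L)))
    ps_stop("event indicator must be 0/1", "schema_error")
  class(outcome) <- unique(c("survival_outcome", class(outcome)))
  outcome
}

as_cov_matrix <- function(covariates) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood over the supplied covariates
#' (Newton-Raphson as implemented in the `survival` package) and returns the
#' coefficient vector with Wald inference. The relative hazard of a patient
#' is `exp(h)` with `h` the centered linear predictor (see
#' [linear_predictor()]).
#'
#' @param covariates numeric matrix or data frame, patients in rows,
#'   covariates in columns; rows aligned with `outcome`.
#' @param outcome a [survival_outcome()] table.
#' @param ties method for tied event times; Efron by default.
#' @return An object of class `cox_model`: coefficients, standard errors,
#'   Wald z and two-sided p per coefficient, log partial likelihood at the
#'   optimum, convergence flag, ties method, and the training covariate
#'   means used for centering.
#' @export
fit_cox <- function(covariates, outcome, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  outcome <- validate_outcome(outcome)
  X <- as_cov_matrix(covariates)
  if (nrow(X) != nrow(outcome))
    ps_stop("covariate rows do not match outcome rows", "schema_error")
  if (sum(outcome$event) < 1L)
    ps_stop("no events in outcome; cannot fit Cox model",
            "insufficient_events_error")
  v <- apply(X, 2L, stats::var)
  if (any(v < 1e-12))
    ps_stop(paste0("zero-variance covariate(s): ",
                   paste(colnames(X)[v < 1e-12], collapse = ", ")),
            "degenerate_covariate_error")
  y <- survival::Surv(outcome$time, outcome$event)
  ctl <- survival::coxph.control(iter.max = 50, eps = 1e-9)
  fit <- survival::coxph.fit(X, y, strata = NULL, offset = NULL,
                             init = NULL, control = ctl, weights = NULL,
                             method = ties,
                             rownames = as.character(seq_len(nrow(X))),
                             resid = FALSE)
  beta <- fit$coefficients
  se <- rep(NA_real_, length(beta))
  ok <- !is.na(beta)
  se[ok] <- sqrt(diag(as.matrix(fit$var))[ok])
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)
  converged <- fit$iter < ctl$iter.max &&
    all(abs(beta[ok]) <= 20) && all(is.finite(se[ok]))
  structure(list(names = colnames(X), coefficients = beta, se = se,
                 z = z, p = p, loglik = fit$loglik[length(fit$loglik)],
                 converged = converged, ties = ties, means = fit$means,
                 n = nrow(X), n_event = sum(outcome$event)),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat("Cox model (", x$ties, " ties), n = ", x$n, ", events = ",
      x$n_event, if (!x$converged) ", NOT converged" else "", "\n", sep = "")
  print(data.frame(coef = x$coefficients, se = x$se, z = x$z, p = x$p,
                   row.names = x$names))
  invisible(x)
}

#' Linear predictor (relative-hazard score) of a fitted Cox model
#'
#' Computes `h = (x - x_bar_train)' beta` for each patient; `x_bar_train`
#' are the covariate means stored in the model at fitting time, so `h` is
#' comparable across leave-one-out folds. Coefficients that were dropped
#' for collinearity contribute zero.
#'
#' @param model a `cox_model` from [fit_cox()].
#' @param covariates matrix/data frame with the model's covariate columns.
#' @return Numeric vector `h`, named by `covariates` row names when present.
#' @export
linear_predictor <- function(model, covariates) {
  X <- as_cov_matrix(covariates)
  if (!all(model$names %in% colnames(X)))
    ps_stop("covariates are missing model columns", "schema_error")
  X <- X[, model$names, drop = FALSE]
  beta <- model$coefficients
  beta[is.na(beta)] <- 0
  h <- drop(sweep(X, 2L, model$means, "-") %*% beta)
  names(h) <- rownames(covariates)
  h
}

#' Log-rank test between survival groups
#'
#' Mantel-Haenszel log-rank test with hypergeometric variance; two-sided
#' p-value from the chi-square distribution with `groups - 1` degrees of
#' freedom.
#'
#' @param groups factor/character of group labels, one per patient.
#' @param outcome a [survival_outcome()] table aligned with `groups`.
#' @return List of class `logrank_result`: `chisq`, `df`, `p`, and per-group
#'   `observed` / `expected` event counts.
#' @export
log_rank_test <- function(groups, outcome) {
  outcome <- validate_outcome(outcome)
  g <- factor(groups)
  g <- droplevels(g)
  if (length(g) != nrow(outcome))
    ps_stop("group labels do not match outcome rows", "schema_error")
  if (nlevels(g) < 2L)
    ps_stop("log-rank test needs at least two non-empty groups",
            "grouping_error")
  if (sum(outcome$event) < 1L)
    ps_stop("no events in outcome", "insufficient_events_error")
  sd <- survival::survdiff(survival::Surv(outcome$time, outcome$event) ~ g)
  df <- length(sd$n) - 1L
  p <- pchisq(sd$chisq, df = df, lower.tail = FALSE)
  structure(list(chisq = unname(sd$chisq), df = df, p = p,
                 observed = setNames(as.vector(sd$obs), levels(g)),
                 expected = setNames(as.vector(sd$exp), levels(g))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chisq = %.4g on %d df, p = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per group; patients censored at an event time
#' are counted at risk for that time.
#'
#' @param outcome a [survival_outcome()] table.
#' @param groups optional group labels; a single curve if omitted.
#' @return A `data.frame` (class `km_curve`) with columns `group`, `time`,
#'   `n_risk`, `n_event`, `surv` -- one row per observed time per group.
#' @export
km_estimate <- function(outcome, groups = NULL) {
  outcome <- validate_outcome(outcome)
  y <- survival::Surv(outcome$time, outcome$event)
  if (is.null(groups)) {
    sf <- survival::survfit(y ~ 1)
    out <- data.frame(group = "all", time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, surv = sf$surv,
                      stringsAsFactors = FALSE)
  } else {
    g <- droplevels(factor(groups))
    if (length(g) != nrow(outcome))
      ps_stop("group labels do not match outcome rows", "schema_error")
    sf <- survival::survfit(y ~ g)
    if (is.null(sf$strata)) {
      out <- data.frame(group = levels(g)[1L], time = sf$time,
                        n_risk = sf$n.risk, n_event = sf$n.event,
                        surv = sf$surv, stringsAsFactors = FALSE)
    } else {
      grp <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
      out <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                        n_event = sf$n.event, surv = sf$surv,
                        stringsAsFactors = FALSE)
    }
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Univariate Cox screen over many features
#'
#' Fits one Cox model per feature and returns the feature's two-sided Wald
#' p-value. With `adjust`, an adjustment-only Cox model is fit first and its
#' linear predictor enters every per-feature fit as a fixed offset, so the
#' screen is conditional on the adjustment covariates. Degenerate
#' (zero-variance) or non-converged features receive the sentinel p = 1 and
#' a warning, keeping the returned vector aligned with the input columns.
#'
#' @param features numeric matrix, patients in rows, features in columns.
#' @param outcome a [survival_outcome()] table aligned with the rows.
#' @param adjust optional numeric matrix of adjustment covariates.
#' @param details if `TRUE` return a data frame with beta/se/z/p and flags
#'   instead of the bare p-value vector.
#' @return Named numeric vector of Wald p-values (or a data frame when
#'   `details = TRUE`).
#' @export
univariate_screen <- function(features, outcome, adjust = NULL,
                              details = FALSE) {
  outcome <- validate_outcome(outcome)
  X <- as_cov_matrix(features)
  if (nrow(X) != nrow(outcome))
    ps_stop("feature rows do not match outcome rows", "schema_error")
  if (anyNA(X))
    ps_stop("features contain missing values", "schema_error")
  if (sum(outcome$event) < 1L)
    ps_stop("no events in outcome", "insufficient_events_error")
  n <- nrow(X)
  offset <- rep(0, n)
  if (!is.null(adjust)) {
    A <- as_cov_matrix(adjust)
    if (nrow(A) != n)
      ps_stop("adjust rows do not match outcome rows", "schema_error")
    afit <- fit_cox(A, outcome)
    offset <- linear_predictor(afit, A)
  }
  ord <- order(outcome$time)
  res <- .cox_screen_cpp(outcome$time[ord], as.integer(outcome$event[ord]),
                         X[ord, , drop = FALSE], as.numeric(offset[ord]))
  p <- 2 * pnorm(-abs(res$beta / res$se))
  bad <- res$degenerate | !res$converged
  if (any(bad)) {
    p[bad] <- 1
    ps_warn(sprintf(
      "%d feature(s) degenerate or non-converged; p set to 1", sum(bad)),
      "screen_degenerate_warning")
  }
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  names(p) <- colnames(X)
  if (!details) return(p)
  data.frame(feature = colnames(X), beta = res$beta, se = res$se,
             z = res$beta / res$se, p = p, converged = res$converged,
             degenerate = res$degenerate, stringsAsFactors = FALSE)
}
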