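# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no stored data.

# small right-censored outcome with iid exponential times
quick_outcome <- function(n, event_p = 0.5, rate = 0.05) {
  survival_outcome(sprintf("P%03d", seq_len(n)),
                   stats::rexp(n, rate),
                   as.integer(stats::runif(n) < event_p))
}

# pure-noise expression matrix, genes x patients
noise_expr <- function(G, n, ids = sprintf("P%03d", seq_len(n))) {
  matrix(stats::rnorm(G * n), G, n,
         dimnames = list(sprintf("G%05d", seq_len(G)), ids))
}

# a small, fast simulation configuration for cohort-level tests
small_config <- function(seed = 1L, ...) {
  sim_config(n_patients = 80L, n_genes = 300L, n_snps = 120L,
             eqtl_spec = list(n = 10L, effect = 1.0, cis_bp = 50000L),
             csnp_spec = list(n = 5L, effect = 0.4, on_eqtl_frac = 0.5),
             seed = seed, ...)
}

# Independent oracle: explicit Cox partial log-likelihood for a single
# covariate with NO tied event times, maximized by golden-section search.
# Used to cross-check the Newton-Raphson fitters.
pl_loglik_1cov <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1L)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_beta_1cov <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(function(b) pl_loglik_1cov(b, time, event, x),
                  interval = interval, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Independent oracle: exhaustive hypergeometric upper tail by enumerating
# every possible draw of size |A| from the universe (combn); feasible for
# N <= ~22.
oracle_overlap_p <- function(N, nA, nB, k) {
  draws <- utils::combn(N, nA)
  inB <- seq_len(nB)  # wlog B = first nB elements
  hits <- apply(draws, 2L, function(d) sum(d %in% inB))
  mean(hits >= k)
}
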