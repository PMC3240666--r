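#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-covariate Cox partial-likelihood maximization, applied independently
// to each column of X, with an optional fixed offset in the linear
// predictor.  Efron approximation for tied event times.  Input must be
// sorted by ascending follow-up time; ties in time are handled by grouping.
//
// Returns beta, se (from the observed information at the optimum),
// log partial likelihood, and flags for convergence / degeneracy.
//
// Newton-Raphson with step-halving; |beta| running past beta_bound is
// treated as monotone-likelihood divergence and flagged non-converged.

struct PLEval {
  double ll, U, I;
};

static PLEval eval_partial(const double beta,
                           const NumericVector& time,
                           const IntegerVector& status,
                           const NumericMatrix& X, const int g,
                           const NumericVector& offset) {
  const int n = time.size();
  double ll = 0.0, U = 0.0, I = 0.0;
  double S0 = 0.0, S1 = 0.0, S2 = 0.0;
  int i = n - 1;
  while (i >= 0) {
    int j = i;
    double D0 = 0, D1 = 0, D2 = 0, xsum = 0, esum = 0;
    int d = 0;
    while (j >= 0 && time[j] == time[i]) {
      const double x = X(j, g);
      const double eta = beta * x + offset[j];
      const double w = std::exp(eta);
      S0 += w; S1 += w * x; S2 += w * x * x;
      if (status[j] == 1) {
        ++d; xsum += x; esum += eta;
        D0 += w; D1 += w * x; D2 += w * x * x;
      }
      --j;
    }
    if (d > 0) {
      ll += esum; U += xsum;
      for (int l = 0; l < d; ++l) {
        const double f = (double)l / d;
        const double s0 = S0 - f * D0;
        const double s1 = S1 - f * D1;
        const double s2 = S2 - f * D2;
        ll -= std::log(s0);
        U -= s1 / s0;
        I += s2 / s0 - (s1 / s0) * (s1 / s0);
      }
    }
    i = j;
  }
  PLEval out; out.ll = ll; out.U = U; out.I = I;
  return out;
}

// [[Rcpp::export(name = ".cox_screen_cpp")]]
List cox_screen_cpp(NumericVector time, IntegerVector status,
                    NumericMatrix X, NumericVector offset,
                    int max_iter = 30, double tol = 1e-8,
                    double beta_bound = 20.0) {
  const int n = time.size();
  const int G = X.ncol();
  NumericVector beta_out(G), se_out(G), ll_out(G);
  LogicalVector conv(G), degen(G);

  for (int g = 0; g < G; ++g) {
    // degeneracy: (near-)zero variance of the covariate
    double mx = 0.0;
    for (int i = 0; i < n; ++i) mx += X(i, g);
    mx /= n;
    double vx = 0.0;
    for (int i = 0; i < n; ++i) { const double d = X(i, g) - mx; vx += d * d; }
    if (vx / n < 1e-12) {
      degen[g] = true; conv[g] = false;
      beta_out[g] = 0.0; se_out[g] = NA_REAL; ll_out[g] = NA_REAL;
      continue;
    }

    double beta = 0.0;
    PLEval cur = eval_partial(beta, time, status, X, g, offset);
    bool converged = false;
    for (int iter = 0; iter < max_iter; ++iter) {
      if (cur.I <= 1e-300) break;                 // flat likelihood
      double step = cur.U / cur.I;
      if (step > 5.0) step = 5.0;                 // damp wild first steps
      if (step < -5.0) step = -5.0;
      double beta_new = beta + step;
      PLEval nxt = eval_partial(beta_new, time, status, X, g, offset);
      int halvings = 0;
      while (nxt.ll < cur.ll - 1e-12 && halvings < 20) {
        step *= 0.5;
        beta_new = beta + step;
        nxt = eval_partial(beta_new, time, status, X, g, offset);
        ++halvings;
      }
      const bool small_score = std::fabs(nxt.U) < 1e-7;
      const bool small_move = std::fabs(beta_new - beta) < tol;
      const bool small_llchange =
        std::fabs(nxt.ll - cur.ll) < 1e-9 * (std::fabs(cur.ll) + 1e-9);
      beta = beta_new; cur = nxt;
      if (std::fabs(beta) > beta_bound) { converged = false; break; }
      if (small_score || small_move || small_llchange) { converged = true; break; }
    }
    beta_out[g] = beta;
    se_out[g] = (cur.I > 0) ? 1.0 / std::sqrt(cur.I) : NA_REAL;
    ll_out[g] = cur.ll;
    conv[g] = converged && std::fabs(beta) <= beta_bound;
    degen[g] = false;
  }

  return List::create(_["beta"] = beta_out, _["se"] = se_out,
                      _["loglik"] = ll_out, _["converged"] = conv,
                      _["degenerate"] = degen);
}
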