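// One-dimensional stochastic surrogates: a continuous-time birth-death walk on
// cluster size n over a prescribed free-energy profile (validation ensemble for
// MFPT analysis) and a Metropolis sampler on a biased 1-D landscape
// (validation surrogate for the CNT umbrella sampler).
#include "icenuc.h"
using namespace Rcpp;

// First-passage times to every level 0..M for n_traj walks starting at 0.
// Rates: up k+, down k+ * exp(beta(G(n) - G(n-1))) (detailed balance against
// pi(n) ~ exp(-beta G(n))); reflecting at 0, absorbing at M.
// [[Rcpp::export]]
NumericMatrix bd_walks_cpp(NumericVector betaG, double kplus, int n_traj,
                           double max_events) {
  int M = betaG.size() - 1;
  NumericMatrix fpt(n_traj, M + 1);
  std::fill(fpt.begin(), fpt.end(), NA_REAL);
  RNGScope scope;
  for (int w = 0; w < n_traj; ++w) {
    int n = 0;
    double t = 0.0;
    fpt(w, 0) = 0.0;
    double ev = 0.0;
    while (n < M && ev < max_events) {
      double a = kplus;
      double b = (n > 0) ? kplus * std::exp(betaG[n] - betaG[n - 1]) : 0.0;
      double rtot = a + b;
      t += exp_rand() / rtot;
      if (unif_rand() * rtot < a) {
        ++n;
        if (!R_finite(fpt(w, n)) || ISNA(fpt(w, n))) fpt(w, n) = t;
      } else {
        --n;
      }
      ev += 1.0;
    }
  }
  return fpt;
}

// Metropolis random walk on n in [0, M] with target ~ exp(-beta_tot(n));
// symmetric integer proposals in [-step, step] \ {0}.
// [[Rcpp::export]]
List metropolis1d_cpp(NumericVector beta_tot, double n_moves, int start,
                      int step) {
  int M = beta_tot.size() - 1;
  NumericVector counts(M + 1);
  int n = start;
  double acc = 0.0;
  RNGScope scope;
  for (double m = 0; m < n_moves; ++m) {
    int dn = (int)std::floor(unif_rand() * (2 * step + 1)) - step;
    int trial = n + dn;
    if (dn != 0 && trial >= 0 && trial <= M) {
      double dE = beta_tot[trial] - beta_tot[n];
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) { n = trial; acc += 1.0; }
    }
    counts[n] += 1.0;
  }
  return List::create(_["counts"] = counts, _["acceptance"] = acc / n_moves,
                      _["final"] = n);
}
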