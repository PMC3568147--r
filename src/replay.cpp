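#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Teacher-forced replay of trial sequences under the grid-based Bayesian
// learner. Rows must be ordered by sequence and trial; a change in seq_id
// resets the belief map to uniform. For each trial the map is first decayed
// (lam * P + (1 - lam) * uniform); the deterministic model prediction for
// that trial is the MAP cell center of the decayed map (NA for the first
// trial of a sequence, (0, 0) fallback when the map is numerically uniform);
// the map is then updated with the observed action and reward fraction via
// the likelihood kernel exp(-kappa * (rhat - r)^2). Storage is column-major
// with rows indexing direction (alpha) and columns curvature (beta); argmax
// ties break to the lowest linear index.
// [[Rcpp::export]]
NumericMatrix replay_predict_cpp(IntegerVector seq_id,
                                 NumericVector exec_alpha,
                                 NumericVector exec_beta,
                                 NumericVector reward_frac,
                                 double lam, double w_alpha, double w_beta,
                                 double kappa, int G) {
  const int n = seq_id.size();
  const double unif = 1.0 / ((double)G * (double)G);
  NumericMatrix pred(n, 2);
  std::vector<double> P((size_t)G * G), Q((size_t)G * G);
  std::vector<double> centers(G), da2(G), db2(G);
  for (int i = 0; i < G; ++i) centers[i] = -1.0 + (2.0 * i + 1.0) / G;

  int cur_seq = NA_INTEGER;
  bool first = true;
  for (int t = 0; t < n; ++t) {
    if (first || seq_id[t] != cur_seq) {
      std::fill(P.begin(), P.end(), unif);
      cur_seq = seq_id[t];
      first = false;
      pred(t, 0) = NA_REAL;
      pred(t, 1) = NA_REAL;
    } else {
      // decay, tracking extrema and argmax of the decayed map
      int kmax = 0;
      double vmax = -1.0, vmin = 2.0;
      for (size_t k = 0; k < P.size(); ++k) {
        double v = lam * P[k] + (1.0 - lam) * unif;
        P[k] = v;
        if (v > vmax) { vmax = v; kmax = (int)k; }
        if (v < vmin) vmin = v;
      }
      if (vmax - vmin <= vmax * 1e-12) {
        pred(t, 0) = 0.0;  // uniform map: no informative mode
        pred(t, 1) = 0.0;
      } else {
        pred(t, 0) = centers[kmax % G];
        pred(t, 1) = centers[kmax / G];
      }
    }
    // update with the observed action and reward
    const double r = reward_frac[t];
    for (int i = 0; i < G; ++i) {
      double da = (exec_alpha[t] - centers[i]) / 2.0;
      da2[i] = w_alpha * da * da;
      double db = (exec_beta[t] - centers[i]) / 2.0;
      db2[i] = w_beta * db * db;
    }
    double s = 0.0;
    for (int j = 0; j < G; ++j) {
      const double bj = db2[j];
      double *Pc = &P[(size_t)j * G];
      double *Qc = &Q[(size_t)j * G];
      for (int i = 0; i < G; ++i) {
        double e = (1.0 - da2[i] - bj) - r;
        double v = Pc[i] * std::exp(-kappa * e * e);
        Qc[i] = v;
        s += v;
      }
    }
    if (R_finite(s) && s > 0.0) {
      const double inv = 1.0 / s;
      for (size_t k = 0; k < P.size(); ++k) P[k] = Q[k] * inv;
    }
    // else: degenerate posterior, keep the (decayed) prior
  }
  colnames(pred) = CharacterVector::create("pred_alpha", "pred_beta");
  return pred;
}
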