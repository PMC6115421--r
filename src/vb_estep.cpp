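#include <Rcpp.h>
using namespace Rcpp;

// Sequential coordinate-ascent E-step sweep for the variational WSBM.
// Each node's responsibility row is updated in turn using the current
// responsibilities of all other nodes, which keeps the evidence lower
// bound non-decreasing (a parallel update would not).
//
// tau      : n x k responsibilities (input; an updated copy is returned)
// X        : n x n binary presence matrix
// W        : n x n weight matrix (only entries with X > 0 are used)
// logprior : n x k log prior assignment probabilities
// elog_theta, e_theta : E[log theta], E[theta] of the Gamma rate posteriors
// elog_lam, ab        : E[log lambda], E[lambda] (= a/b) of the weight
//                       precision posteriors
// m, inv_kappa        : posterior weight means and 1/kappa
// alpha    : mixing weight between presence and weight likelihoods
// [[Rcpp::export]]
NumericMatrix vb_estep_sweep(NumericMatrix tau, NumericMatrix X,
                             NumericMatrix W, NumericMatrix logprior,
                             NumericMatrix elog_theta, NumericMatrix e_theta,
                             NumericMatrix elog_lam, NumericMatrix ab,
                             NumericMatrix m, NumericMatrix inv_kappa,
                             double alpha) {
  const int n = tau.nrow(), k = tau.ncol();
  const double LOG2PI = 1.837877066409345483560659472811;
  NumericMatrix t2(clone(tau));
  std::vector<double> S1(k), S2(k), S3(k), S4(k), sc(k);

  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < k; ++s) { S1[s] = S2[s] = S3[s] = S4[s] = 0.0; }
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double x = X(j, i);
      const double w = W(j, i);
      for (int s = 0; s < k; ++s) {
        const double t = t2(j, s);
        S1[s] += t;
        if (x > 0) { S2[s] += t; S3[s] += t * w; S4[s] += t * w * w; }
      }
    }
    double mx = -1e300;
    for (int r = 0; r < k; ++r) {
      double v = logprior(i, r);
      for (int s = 0; s < k; ++s) {
        const double pois = S2[s] * elog_theta(r, s) - S1[s] * e_theta(r, s);
        const double ms = m(r, s);
        const double quad = S4[s] - 2.0 * ms * S3[s] + ms * ms * S2[s];
        const double norm = 0.5 * (elog_lam(r, s) - LOG2PI) * S2[s]
                            - 0.5 * (ab(r, s) * quad + inv_kappa(r, s) * S2[s]);
        v += alpha * pois + (1.0 - alpha) * norm;
      }
      sc[r] = v;
      if (v > mx) mx = v;
    }
    double tot = 0.0;
    for (int r = 0; r < k; ++r) { sc[r] = std::exp(sc[r] - mx); tot += sc[r]; }
    for (int r = 0; r < k; ++r) t2(i, r) = sc[r] / tot;
  }
  return t2;
}
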