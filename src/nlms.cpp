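#include <Rcpp.h>
using namespace Rcpp;

// Normalized least-mean-squares adaptive identification of an FIR system.
// Per-sample update: w <- w + mu * e_n * x_n / (||x_n||^2 + delta), with
// e_n = y_n - w' x_n and x_n the last L excitation samples (zero history at
// the start of each pass; taps carry over between passes).
// [[Rcpp::export(name = ".nlms_core")]]
List nlms_core(NumericVector x, NumericVector y, int L, double mu,
               double delta, int passes) {
  const int n = x.size();
  std::vector<double> w(L, 0.0);
  NumericVector err2(static_cast<R_xlen_t>(n) * passes);
  for (int p = 0; p < passes; ++p) {
    double norm = 0.0;
    for (int t = 0; t < n; ++t) {
      norm += x[t] * x[t];
      if (t >= L) norm -= x[t - L] * x[t - L];
      if (norm < 0.0) norm = 0.0;  // guard against rounding drift
      const int kmax = std::min(t + 1, L);
      double d = 0.0;
      for (int k = 0; k < kmax; ++k) d += w[k] * x[t - k];
      const double e = y[t] - d;
      err2[static_cast<R_xlen_t>(p) * n + t] = e * e;
      const double g = mu * e / (norm + delta);
      for (int k = 0; k < kmax; ++k) w[k] += g * x[t - k];
    }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["err2"] = err2);
}
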