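#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM:
//   min_w 1/2 ||w||^2 + C * sum_i max(0, 1 - y_i * w.x_i)
// The bias is carried as an augmented constant feature appended by the
// R wrapper, so d here already includes it.  Deterministic cyclic order
// (no random permutation) so fits are reproducible bit-for-bit.
// Stops when the maximal projected-gradient violation in a sweep falls
// below tol, or after max_sweeps.
// [[Rcpp::export(name = ".svm_dual_cd")]]
NumericVector svm_dual_cd(NumericMatrix X, NumericVector y, double C,
                          double tol, int max_sweeps) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> alpha(n, 0.0), w(d, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;   // all-zero row: alpha stays put
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::abs(PG) > max_viol) max_viol = std::abs(PG);
      if (std::abs(PG) > 1e-14) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        const double delta = a_new - alpha[i];
        if (delta != 0.0) {
          const double dy = delta * y[i];
          for (int j = 0; j < d; ++j) w[j] += dy * X(i, j);
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
  NumericVector out(d + n);
  for (int j = 0; j < d; ++j) out[j] = w[j];
  for (int i = 0; i < n; ++i) out[d + i] = alpha[i];
  return out;
}
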