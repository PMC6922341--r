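#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trapezoidal quadrature moments of the unnormalized cusp density
// exp(alpha z + beta z^2/2 - z^4/4) row-wise over (alpha, beta) pairs.
// Returns log normalizing constants and the first two moments without
// materializing the n x m exponent matrix.
// [[Rcpp::export]]
List cusp_moments_cpp(NumericVector alpha, NumericVector beta,
                      NumericVector z) {
  const int n = alpha.size();
  const int m = z.size();
  if (beta.size() != n) stop("alpha and beta must have equal length");
  if (m < 3) stop("quadrature grid too small");
  const double h = z[1] - z[0];
  std::vector<double> z2(m), z4(m);
  for (int j = 0; j < m; ++j) {
    z2[j] = z[j] * z[j] / 2.0;
    z4[j] = z2[j] * z2[j]; // (z^2/2)^2 = z^4/4
  }
  NumericVector log_psi(n), ey(n), ey2(n);
  for (int i = 0; i < n; ++i) {
    const double a = alpha[i], b = beta[i];
    double gmax = R_NegInf;
    for (int j = 0; j < m; ++j) {
      double g = a * z[j] + b * z2[j] - z4[j];
      if (g > gmax) gmax = g;
    }
    double s0 = 0.0, s1 = 0.0, s2 = 0.0;
    for (int j = 0; j < m; ++j) {
      double e = std::exp(a * z[j] + b * z2[j] - z4[j] - gmax);
      double w = (j == 0 || j == m - 1) ? 0.5 : 1.0;
      s0 += w * e;
      s1 += w * e * z[j];
      s2 += w * e * z[j] * z[j];
    }
    log_psi[i] = -(gmax + std::log(s0 * h));
    ey[i] = s1 / s0;
    ey2[i] = s2 / s0;
  }
  return List::create(_["log_psi"] = log_psi, _["ey"] = ey, _["ey2"] = ey2);
}
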