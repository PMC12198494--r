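#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rectangular Minkowski-q distance block between the rows of a (n x p) and
// b (m x p). Feature-major loops so the n x m accumulator stays cache-hot;
// q = 1 and q = 2 get branch-free fast paths since they carry the whole
// classifier workload.
// [[Rcpp::export]]
NumericMatrix cross_minkowski_cpp(NumericMatrix a, NumericMatrix b, double q) {
  const int n = a.nrow(), m = b.nrow(), p = a.ncol();
  if (b.ncol() != p)
    stop("feature count mismatch: %d columns vs %d columns", p, b.ncol());
  if (q < 1) stop("Minkowski order q must be >= 1, got %f", q);
  NumericMatrix d(n, m);
  double *dp = REAL(d);
  const double *ap = REAL(a), *bp = REAL(b);
  for (int l = 0; l < p; ++l) {
    const double *al = ap + (R_xlen_t)l * n;
    const double *bl = bp + (R_xlen_t)l * m;
    for (int j = 0; j < m; ++j) {
      const double bv = bl[j];
      double *dj = dp + (R_xlen_t)j * n;
      if (q == 1.0) {
        for (int i = 0; i < n; ++i) dj[i] += std::abs(al[i] - bv);
      } else if (q == 2.0) {
        for (int i = 0; i < n; ++i) {
          const double u = al[i] - bv;
          dj[i] += u * u;
        }
      } else {
        for (int i = 0; i < n; ++i) dj[i] += std::pow(std::abs(al[i] - bv), q);
      }
    }
  }
  if (q != 1.0) {
    const double inv = 1.0 / q;
    const R_xlen_t nm = (R_xlen_t)n * m;
    if (q == 2.0) {
      for (R_xlen_t k = 0; k < nm; ++k) dp[k] = std::sqrt(dp[k]);
    } else {
      for (R_xlen_t k = 0; k < nm; ++k) dp[k] = std::pow(dp[k], inv);
    }
  }
  return d;
}
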