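#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact linear sum assignment by the primal-dual (potential-maintaining)
// shortest-augmenting-path Hungarian algorithm, O(n^3). Unlike off-the-shelf
// primal solvers, this keeps the dual variables, which at termination are
// Kantorovich potentials for the discrete 1-Wasserstein problem:
//   u[i] + v[j] <= c[i][j] for all i,j (dual feasibility),
//   u[i] + v[perm[i]] == c[i][perm[i]] (complementary slackness),
//   sum(u) + sum(v) == total assignment cost (zero duality gap).
// Requires a finite nonnegative cost matrix (distances), which guarantees
// feasibility also holds for rows not yet inserted during the sweep.
// [[Rcpp::export]]
List lap_hungarian_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n)
    stop("cost matrix must be square (%d x %d): balance the classes first",
         n, cost.ncol());
  const double *c = REAL(cost);
  for (R_xlen_t k = 0; k < (R_xlen_t)n * n; ++k)
    if (!R_FINITE(c[k]) || c[k] < 0)
      stop("cost matrix entries must be finite and nonnegative");

  const double INF = std::numeric_limits<double>::infinity();
  // 1-based with a virtual column 0, classic formulation
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  std::vector<double> minv(n + 1);
  std::vector<char> used(n + 1);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(used.begin(), used.end(), 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = 0;
      double delta = INF;
      const double ui0 = u[i0];
      const double *ci0 = c + (i0 - 1);  // row i0-1, column-major stride n
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = ci0[(R_xlen_t)(j - 1) * n] - ui0 - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }

  IntegerVector perm(n);
  double total = 0.0;
  for (int j = 1; j <= n; ++j) {
    perm[p[j] - 1] = j;                       // row p[j] assigned to column j
    total += c[(p[j] - 1) + (R_xlen_t)(j - 1) * n];
  }
  NumericVector psi(n), phi(n);
  for (int i = 1; i <= n; ++i) psi[i - 1] = u[i];
  for (int j = 1; j <= n; ++j) phi[j - 1] = v[j];
  return List::create(_["perm"] = perm, _["psi"] = psi, _["phi"] = phi,
                      _["total_cost"] = total);
}
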