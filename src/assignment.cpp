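#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact rectangular min-cost assignment (Hungarian algorithm with
// potentials, shortest-augmenting-path form). Requires nrow <= ncol.
// Returns a 1-based column index for every row. O(n^2 * m).
// Infeasible edges are encoded by the caller as a large finite penalty.
// [[Rcpp::export]]
IntegerVector solve_assignment_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  const int m = cost.ncol();
  if (n == 0) return IntegerVector(0);
  if (n > m) stop("assignment requires nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  // 1-based arrays; p[j] = row matched to column j (0 = free)
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0), minv(m + 1);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  std::vector<char> used(m + 1);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(used.begin(), used.end(), 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = -1;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      if (j1 < 0) stop("assignment infeasible");
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else         { minv[j] -= delta; }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }

  IntegerVector match(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) match[p[j] - 1] = j;
  return match;
}
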