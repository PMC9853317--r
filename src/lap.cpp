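#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact minimum-cost rectangular assignment (Jonker-Volgenant style shortest
// augmenting paths with dual potentials). Rows must not exceed columns; every
// row is assigned to a distinct column. Entries >= big_threshold are treated
// as forbidden; if the optimum is forced through one, the caller falls back
// to an unrestricted problem.
//
// Classic O(n^2 m) successive-shortest-path formulation; deterministic.

// [[Rcpp::export(name = ".lap_solve")]]
List lap_solve(NumericMatrix cost) {
  const int n = cost.nrow();
  const int m = cost.ncol();
  if (n > m) stop("lap_solve needs nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) {
          minv[j] = cur;
          way[j] = j0;
        }
        if (minv[j] < delta) {
          delta = minv[j];
          j1 = j;
        }
      }
      if (j1 < 0) stop("assignment infeasible");
      for (int j = 0; j <= m; ++j) {
        if (used[j]) {
          u[p[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }

  IntegerVector rowsol(n);
  double total = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (p[j] > 0) rowsol[p[j] - 1] = j;
  }
  for (int i = 0; i < n; ++i) total += cost(i, rowsol[i] - 1);
  return List::create(_["col"] = rowsol, _["total"] = total);
}
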