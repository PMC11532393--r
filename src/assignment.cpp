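#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Exact solver for the rectangular assignment problem
//
//   min_z sum_ij z_ij c_ij   s.t.  sum_j z_ij = 1 (all rows),
//                                  sum_i z_ij <= 1 (all cols),
//                                  z binary,  nrow <= ncol.
//
// The constraint matrix is totally unimodular, so the LP relaxation is
// integral and a shortest-augmenting-path / dual-potential method finds the
// exact optimum in O(n^2 m). One row is assigned per outer iteration by
// growing an alternating tree of reduced-cost-shortest paths (Dijkstra with
// potentials u, v) until a free column is reached, then augmenting.

// [[Rcpp::export]]
IntegerVector cpp_assign(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n == 0) return IntegerVector(0);
  if (n > m) stop("cpp_assign: nrow must not exceed ncol");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n, 0.0), v(m, 0.0);
  std::vector<int> col4row(n, -1), row4col(m, -1);

  for (int curRow = 0; curRow < n; ++curRow) {
    std::vector<double> shortest(m, INF);
    std::vector<int> path(m, -1);
    std::vector<char> SR(n, 0), SC(m, 0);
    double minVal = 0.0;
    int i = curRow, sink = -1;

    while (sink == -1) {
      SR[i] = 1;
      double lowest = INF;
      int jBest = -1;
      for (int j = 0; j < m; ++j) {
        if (SC[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { shortest[j] = r; path[j] = i; }
        // prefer free columns on ties so augmentation terminates promptly
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1)) {
          lowest = shortest[j];
          jBest = j;
        }
      }
      minVal = lowest;
      if (jBest < 0 || !R_finite(minVal))
        stop("cpp_assign: infeasible instance (non-finite costs?)");
      SC[jBest] = 1;
      if (row4col[jBest] == -1) sink = jBest; else i = row4col[jBest];
    }

    u[curRow] += minVal;
    for (int k = 0; k < n; ++k)
      if (SR[k] && k != curRow) u[k] += minVal - shortest[col4row[k]];
    for (int j = 0; j < m; ++j)
      if (SC[j]) v[j] -= minVal - shortest[j];

    int j = sink;
    while (true) {
      int ii = path[j];
      row4col[j] = ii;
      std::swap(col4row[ii], j);
      if (ii == curRow) break;
    }
  }

  IntegerVector out(n);
  for (int k = 0; k < n; ++k) out[k] = col4row[k] + 1;  // 1-based for R
  return out;
}
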