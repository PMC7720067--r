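#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact open-path travelling salesman by Held-Karp dynamic programming.
// dp[S][j] = length of the shortest path that visits exactly the vertex
// subset S and ends at j (the start is free), built up by subset size:
//   dp[{j}][j] = 0
//   dp[S][j]   = min_{l in S\{j}} dp[S\{j}][l] + d(l, j)
// The optimal open-path cost is min_j dp[V][j], i.e. the minimum over all
// endpoint pairs. O(2^n * n^2) time, O(2^n * n) memory: n is capped by the
// caller (default 15 -> ~4 MB of doubles).

// [[Rcpp::export]]
List held_karp_cpp(NumericMatrix d) {
  const int n = d.nrow();
  if (n < 2) stop("need at least 2 vertices");
  if (n > 24) stop("instance too large for exact DP");
  const int full = 1 << n;
  std::vector<double> dp((size_t)full * n, R_PosInf);
  for (int j = 0; j < n; ++j) dp[((size_t)1 << j) * n + j] = 0.0;

  for (int S = 1; S < full; ++S) {
    if ((S & (S - 1)) == 0) continue;  // singleton: base case
    for (int j = 0; j < n; ++j) {
      if (!((S >> j) & 1)) continue;
      const int Sprev = S ^ (1 << j);
      double best = R_PosInf;
      for (int l = 0; l < n; ++l) {
        if (!((Sprev >> l) & 1)) continue;
        const double v = dp[(size_t)Sprev * n + l] + d(l, j);
        if (v < best) best = v;
      }
      dp[(size_t)S * n + j] = best;
    }
  }

  const int Sfull = full - 1;
  double L = R_PosInf;
  for (int j = 0; j < n; ++j) L = std::min(L, dp[(size_t)Sfull * n + j]);

  // Backtrack from the terminal vertex: at each step the predecessor is a
  // vertex satisfying dp[S][j] = dp[S\{j}][l] + d(l, j); on floating-point
  // ties prefer the smallest index, for reproducibility.
  const double eps = 1e-9 * std::max(1.0, std::fabs(L));
  std::vector<int> path(n);
  int S = Sfull, j = -1;
  for (int cand = 0; cand < n; ++cand) {
    if (dp[(size_t)S * n + cand] <= L + eps) { j = cand; break; }
  }
  path[n - 1] = j;
  for (int pos = n - 2; pos >= 0; --pos) {
    const int Sprev = S ^ (1 << j);
    const double target = dp[(size_t)S * n + j];
    int l = -1;
    for (int cand = 0; cand < n; ++cand) {
      if (!((Sprev >> cand) & 1)) continue;
      if (std::fabs(dp[(size_t)Sprev * n + cand] + d(cand, j) - target) <=
          eps) { l = cand; break; }
    }
    if (l < 0) stop("backtracking failed (numerical)");
    path[pos] = l;
    S = Sprev;
    j = l;
  }

  IntegerVector ord(n);
  for (int i = 0; i < n; ++i) ord[i] = path[i] + 1;
  return List::create(_["order"] = ord, _["cost"] = L);
}
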