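#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact minimum-agony ranking of a weighted directed graph by dynamic
// programming over level sets.
//
// A ranking assigns each node an integer level r(v) in 1..n; an arc u->v
// incurs agony w * max(0, r(u) - r(v) + 1). Decomposing over thresholds t,
// an arc contributes w at every level t with r(v) <= t <= r(u), so
//
//   total agony = sum_t  w( { arcs u->v : r(v) <= t <= r(u) } ).
//
// Building levels bottom-up with S = nodes placed strictly below level t and
// A = nodes placed at level t, the threshold-t contribution is
//   base(S) + sum_{v in A} W_S(v)
// with base(S) = total weight of arcs u->v, u not in S, v in S, and
// W_S(v) = total weight of arcs u->v with u,v not in S. This depends only on
// (S, A), giving an O(n * 3^n) exact DP (n <= 16 enforced by the caller).
//
// lo/hi give per-node admissible level windows (1-based); they are used by
// the caller to fix nodes at levels when computing the lexicographically
// smallest co-optimal ranking. Empty levels are allowed (A may be empty);
// they still pay base(S) for that threshold.

// [[Rcpp::export]]
List agony_dp(IntegerVector arc_u, IntegerVector arc_v, NumericVector arc_w,
              int n, IntegerVector lo, IntegerVector hi) {
  if (n < 1 || n > 16) stop("agony_dp supports 1..16 nodes");
  const int full = (1 << n) - 1;
  const int nS = 1 << n;
  const int na = arc_u.size();
  const double INF = R_PosInf;

  std::vector<double> dp_cur(nS, INF), dp_next(nS, INF);
  std::vector<int> choice((size_t)(n + 1) * nS, -1);
  std::vector<double> W(n), sums(nS);
  std::vector<int> maskof(nS), bits(n);
  dp_cur[0] = 0.0;

  for (int t = 1; t <= n; ++t) {
    std::fill(dp_next.begin(), dp_next.end(), INF);
    int allow = 0, mustby = 0;
    for (int g = 0; g < n; ++g) {
      if (lo[g] <= t && t <= hi[g]) allow |= (1 << g);
      if (hi[g] <= t) mustby |= (1 << g);
    }
    for (int S = 0; S <= full; ++S) {
      double d0 = dp_cur[S];
      if (!R_finite(d0)) continue;
      int comp = full & ~S;
      int must = comp & mustby;
      if ((must & ~allow) != 0) continue;  // a node ran out of levels
      int freeM = comp & allow & ~must;

      double base = 0.0;
      for (int g = 0; g < n; ++g) W[g] = 0.0;
      for (int a = 0; a < na; ++a) {
        int u = arc_u[a], v = arc_v[a];
        if (!((S >> u) & 1)) {
          if ((S >> v) & 1) base += arc_w[a];
          else W[v] += arc_w[a];
        }
      }
      double wmust = 0.0;
      for (int g = 0; g < n; ++g) if ((must >> g) & 1) wmust += W[g];

      int nb = 0;
      for (int g = 0; g < n; ++g) if ((freeM >> g) & 1) bits[nb++] = g;
      int nsub = 1 << nb;
      maskof[0] = 0; sums[0] = 0.0;
      for (int j = 0; j < nsub; ++j) {
        if (j > 0) {
          int p = __builtin_ctz(j);
          int pj = j & (j - 1);
          maskof[j] = maskof[pj] | (1 << bits[p]);
          sums[j] = sums[pj] + W[bits[p]];
        }
        int A = maskof[j] | must;
        int S2 = S | A;
        double cost = d0 + base + sums[j] + wmust;
        if (cost < dp_next[S2]) {
          dp_next[S2] = cost;
          choice[(size_t)t * nS + S2] = A;
        }
      }
    }
    std::swap(dp_cur, dp_next);
  }

  double total = dp_cur[full];
  IntegerVector level(n, NA_INTEGER);
  if (R_finite(total)) {
    int S = full;
    for (int t = n; t >= 1; --t) {
      int A = choice[(size_t)t * nS + S];
      if (A < 0) stop("internal error: broken DP traceback");
      for (int g = 0; g < n; ++g) if ((A >> g) & 1) level[g] = t;
      S &= ~A;
    }
    if (S != 0) stop("internal error: traceback left nodes unplaced");
  }
  return List::create(_["total"] = total, _["level"] = level);
}
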