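#include <Rcpp.h>
using namespace Rcpp;

// Fitting (glocal) alignment of a query restriction-fragment list against a
// reference fragment list by dynamic programming over block decompositions.
//
// A block matches a run of <=delta_max query fragments against a run of
// <=delta_max reference fragments.  Its cost is a chi-square style sizing term
//   (sum_q - sum_r)^2 / (2 * (sigma_rel * sum_r)^2)
// plus cut_penalty per unmatched interior cut, i.e. (nq-1)+(nr-1).
//
// Blocks containing a terminal query fragment are boundary blocks: a contig
// end is not a restriction cut, so the terminal fragment is matched one-sided.
// A boundary block pays no sizing cost when the reference side is at least as
// large (the contig ends inside the reference fragment) and pays the usual
// sizing cost only for query overhang (sum_q > sum_r).
//
// The query is consumed end to end; the reference window is free on both
// sides.  D[i][j] = minimal cost of aligning the first i query fragments with
// the last block ending at reference fragment j; D[0][j] = 0 for every j.
//
// Returns the final DP row (cost of a complete alignment ending at each
// reference fragment) plus traceback matrices giving, for each (i, j), the
// block shape (a = query fragments, b = reference fragments) that attains
// D[i][j].

// [[Rcpp::export(name = ".rmap_fit_dp")]]
List rmap_fit_dp(NumericVector q, NumericVector r, double sigma_rel,
                 double cut_penalty, int delta_max) {
  const int m = q.size(), n = r.size();
  if (m < 1 || n < 1) stop("empty fragment list");
  std::vector<double> qc(m + 1, 0.0), rc(n + 1, 0.0);
  for (int i = 0; i < m; ++i) qc[i + 1] = qc[i] + q[i];
  for (int j = 0; j < n; ++j) rc[j + 1] = rc[j] + r[j];

  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix D(m + 1, n + 1);
  IntegerMatrix TA(m + 1, n + 1), TB(m + 1, n + 1);
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) D(i, j) = (i == 0) ? 0.0 : INF;

  for (int i = 1; i <= m; ++i) {
    const int amax = std::min(delta_max, i);
    for (int j = 1; j <= n; ++j) {
      const int bmax = std::min(delta_max, j);
      double best = INF;
      int besta = 0, bestb = 0;
      for (int a = 1; a <= amax; ++a) {
        const bool boundary = (i - a == 0) || (i == m);
        const double sq = qc[i] - qc[i - a];
        for (int b = 1; b <= bmax; ++b) {
          const double prev = D(i - a, j - b);
          if (prev == INF) continue;
          const double sr = rc[j] - rc[j - b];
          const double d = sq - sr;
          double sizing = 0.0;
          if (!boundary || d > 0) {
            const double denom = sigma_rel * sr;
            sizing = d * d / (2.0 * denom * denom);
          }
          const double cost = prev + sizing + cut_penalty * ((a - 1) + (b - 1));
          if (cost < best) { best = cost; besta = a; bestb = b; }
        }
      }
      D(i, j) = best;
      TA(i, j) = besta;
      TB(i, j) = bestb;
    }
  }

  NumericVector last(n);
  for (int j = 1; j <= n; ++j) last[j - 1] = D(m, j);
  return List::create(_["cost_by_end"] = last, _["ta"] = TA, _["tb"] = TB);
}
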