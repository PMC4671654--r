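#include <Rcpp.h>
using namespace Rcpp;

// Global dynamic-programming alignment of two ordered restriction maps.
//
// The alignment is a sequence of blocks pairing a run of a query fragments
// with a run of b reference fragments (1 <= a, b <= delta).  Runs model
// missed cuts (b > 1: reference cuts absent from the query) and false cuts
// (a > 1: spurious query cuts).  Block cost is a chi-square sizing term
// (Sq - Sr)^2 / (2 (sigma_rel * Sr)^2) plus c_cut * (a - 1 + b - 1).
//
// Returns the minimum total cost and the block decomposition.

// [[Rcpp::export(name = ".rmap_align_cpp")]]
List rmap_align_cpp(NumericVector q, NumericVector r,
                    double sigma_rel, double c_cut, int delta) {
  const int n = q.size(), m = r.size();
  const double INF = R_PosInf;
  NumericMatrix D(n + 1, m + 1);
  IntegerMatrix choiceA(n + 1, m + 1), choiceB(n + 1, m + 1);
  std::fill(D.begin(), D.end(), INF);
  D(0, 0) = 0.0;

  // prefix sums
  std::vector<double> Q(n + 1, 0.0), Rr(m + 1, 0.0);
  for (int i = 0; i < n; ++i) Q[i + 1] = Q[i] + q[i];
  for (int j = 0; j < m; ++j) Rr[j + 1] = Rr[j] + r[j];

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = INF;
      int ba = 0, bb = 0;
      for (int a = 1; a <= delta && a <= i; ++a) {
        for (int b = 1; b <= delta && b <= j; ++b) {
          double prev = D(i - a, j - b);
          if (!R_FINITE(prev)) continue;
          double sq = Q[i] - Q[i - a];
          double sr = Rr[j] - Rr[j - b];
          double sd = sigma_rel * sr;
          double size_cost = (sd > 0.0)
            ? (sq - sr) * (sq - sr) / (2.0 * sd * sd)
            : (sq == sr ? 0.0 : INF);
          if (!R_FINITE(size_cost)) continue;
          double cost = prev + size_cost + c_cut * (a - 1 + b - 1);
          if (cost < best) { best = cost; ba = a; bb = b; }
        }
      }
      D(i, j) = best;
      choiceA(i, j) = ba;
      choiceB(i, j) = bb;
    }
  }

  double total = D(n, m);
  std::vector<int> qs, qe, rs, re;
  if (R_FINITE(total)) {
    int i = n, j = m;
    while (i > 0 && j > 0) {
      int a = choiceA(i, j), b = choiceB(i, j);
      qs.push_back(i - a + 1); qe.push_back(i);
      rs.push_back(j - b + 1); re.push_back(j);
      i -= a; j -= b;
    }
    std::reverse(qs.begin(), qs.end()); std::reverse(qe.begin(), qe.end());
    std::reverse(rs.begin(), rs.end()); std::reverse(re.begin(), re.end());
  }
  return List::create(
    _["cost"] = total,
    _["q_start"] = wrap(qs), _["q_end"] = wrap(qe),
    _["r_start"] = wrap(rs), _["r_end"] = wrap(re));
}
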