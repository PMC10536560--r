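#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact Fisher-Jenks optimal 1-D classification.
//
// Works on sorted distinct values with multiplicities. Minimizes the total
// within-class sum of squared deviations from class means over all
// partitions of the sorted sequence into k contiguous nonempty classes.
//
// A suffix dynamic program T[c][i] = optimal cost of splitting values
// i..n-1 into c classes is filled with the divide-and-conquer argmin
// technique (the SSE interval cost is Monge, so the optimal split index is
// monotone in i), giving O(k n log n) instead of O(k n^2). Reconstruction
// walks left to right taking the smallest feasible boundary at each step,
// so among equal-cost optima the partition whose first class is smallest
// wins (deterministic tie rule).

namespace {

struct Cost {
  std::vector<double> W, S, S2;  // prefix sums of weight, w*x, w*x^2
  explicit Cost(const std::vector<double>& x, const std::vector<double>& w) {
    size_t n = x.size();
    W.assign(n + 1, 0.0); S.assign(n + 1, 0.0); S2.assign(n + 1, 0.0);
    for (size_t i = 0; i < n; ++i) {
      W[i + 1] = W[i] + w[i];
      S[i + 1] = S[i] + w[i] * x[i];
      S2[i + 1] = S2[i] + w[i] * x[i] * x[i];
    }
  }
  // SSE of class spanning value indices [i, j], 0-based inclusive
  double operator()(int i, int j) const {
    double ww = W[j + 1] - W[i];
    double s = S[j + 1] - S[i];
    double s2 = S2[j + 1] - S2[i];
    double c = s2 - (s * s) / ww;
    return c > 0.0 ? c : 0.0;
  }
};

// Fill layer c of the suffix DP over i in [ilo, ihi] with the optimal
// last-class-start... (here: first-class end) b constrained to [blo, bhi].
void solve_layer(int c, int n, const Cost& cost,
                 const std::vector<double>& Tprev, std::vector<double>& Tcur,
                 int ilo, int ihi, int blo, int bhi) {
  if (ilo > ihi) return;
  int im = (ilo + ihi) / 2;
  double best = std::numeric_limits<double>::infinity();
  int bbest = -1;
  int bmax = std::min(bhi, n - c);  // leave c-1 values for remaining classes
  for (int b = std::max(blo, im); b <= bmax; ++b) {
    double v = cost(im, b) + Tprev[b + 1];
    if (v < best) { best = v; bbest = b; }
  }
  Tcur[im] = best;
  solve_layer(c, n, cost, Tprev, Tcur, ilo, im - 1, blo, bbest);
  solve_layer(c, n, cost, Tprev, Tcur, im + 1, ihi, bbest, bhi);
}

}  // namespace

// [[Rcpp::export(name = ".jenks_dp")]]
Rcpp::List jenks_dp(Rcpp::NumericVector values, Rcpp::NumericVector weights,
                    int k) {
  int n = values.size();
  if (k < 2) Rcpp::stop("k must be >= 2");
  if (n < k) Rcpp::stop("need at least k distinct values");
  std::vector<double> x(values.begin(), values.end());
  std::vector<double> w(weights.begin(), weights.end());
  Cost cost(x, w);

  // T[c][i], i in [0, n-c]; T[c][n - c + 1 ..] unused (set +inf)
  std::vector<std::vector<double>> T(
      k + 1, std::vector<double>(n + 1,
                                 std::numeric_limits<double>::infinity()));
  T[0][n] = 0.0;  // zero classes over empty suffix
  for (int i = n - 1; i >= 0; --i) T[1][i] = cost(i, n - 1);
  for (int c = 2; c <= k; ++c)
    solve_layer(c, n, cost, T[c - 1], T[c], 0, n - c, 0, n - c);

  // Left-to-right reconstruction; exact equality holds because the same
  // floating-point expression produced T[c][i] in solve_layer.
  std::vector<int> bounds;  // index of last value of classes 1..k-1
  int i = 0;
  for (int c = k; c >= 2; --c) {
    int bmax = n - c;
    int bsel = -1;
    for (int b = i; b <= bmax; ++b) {
      if (cost(i, b) + T[c - 1][b + 1] == T[c][i]) { bsel = b; break; }
    }
    if (bsel < 0) Rcpp::stop("internal error: no boundary reproduces DP cost");
    bounds.push_back(bsel);
    i = bsel + 1;
  }

  Rcpp::NumericVector breaks(k - 1);
  for (int j = 0; j < k - 1; ++j) breaks[j] = x[bounds[j]];
  return Rcpp::List::create(Rcpp::Named("breaks") = breaks,
                            Rcpp::Named("cost") = T[k][0]);
}
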