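// Grid mutual-information search used by the maximal information
// coefficient (MIC).
//
// For a fixed partition of the "row" axis into `nrows` bins, the optimal
// partition of the "column" axis into at most L bins is found by exact
// dynamic programming (column scores are additive in the columns of the
// contingency table).  The row partition itself is either enumerated
// exactly over all rank-based cut placements (when there are at most
// `exact_limit` of them) or fixed to the rank equipartition -- the
// standard MINE approximation.
//
// All mutual information values returned here are in nats; callers
// rescale or normalize.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// stable order of v: ties keep original order (deterministic rank cuts)
std::vector<int> stable_order(const NumericVector& v) {
  std::vector<int> idx(v.size());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return idx;
}

inline double nlogn(double p) { return p > 0.0 ? p * std::log(p) : 0.0; }

// Given row labels (0..nrows-1) per point and the column-axis order,
// fill best[l-1] (l = 1..max_cols) with max over <=l-column partitions of
//   H(rows) + sum_cols [ -(c/n)log(c/n) + sum_r (c_r/n)log(c_r/n) ]
// i.e. the grid mutual information, taking elementwise max with the
// incoming contents of `best`.
void dp_columns(const std::vector<int>& ord_a,
                const std::vector<int>& rows,
                int nrows, int max_cols,
                std::vector<double>& best) {
  const int n = (int)ord_a.size();
  const double dn = (double)n;

  // cumulative row counts over the column-axis order
  std::vector<int> cum((n + 1) * nrows, 0);
  for (int p = 0; p < n; ++p) {
    const int r = rows[ord_a[p]];
    for (int k = 0; k < nrows; ++k)
      cum[(p + 1) * nrows + k] = cum[p * nrows + k];
    cum[(p + 1) * nrows + r] += 1;
  }

  double hrows = 0.0;
  for (int k = 0; k < nrows; ++k)
    hrows -= nlogn(cum[n * nrows + k] / dn);

  // score(i, j): additive contribution of column (i, j]
  std::vector<double> score((size_t)(n + 1) * (n + 1), 0.0);
  for (int i = 0; i < n; ++i) {
    const int* ci = &cum[i * nrows];
    for (int j = i + 1; j <= n; ++j) {
      const int* cj = &cum[j * nrows];
      double s = -nlogn((j - i) / dn);
      for (int k = 0; k < nrows; ++k)
        s += nlogn((cj[k] - ci[k]) / dn);
      score[(size_t)i * (n + 1) + j] = s;
    }
  }

  const double NEG = -1e300;
  std::vector<double> prev(n + 1, NEG), cur(n + 1, NEG);
  // l = 1
  for (int j = 1; j <= n; ++j) prev[j] = score[j];
  if (best[0] < hrows + prev[n]) best[0] = hrows + prev[n];
  for (int l = 2; l <= max_cols; ++l) {
    for (int j = 1; j <= n; ++j) {
      double m = prev[j];  // allows fewer than l columns implicitly
      for (int i = l - 1; i < j; ++i) {
        const double v = prev[i] + score[(size_t)i * (n + 1) + j];
        if (v > m) m = v;
      }
      cur[j] = m;
    }
    std::swap(prev, cur);
    if (best[l - 1] < hrows + prev[n]) best[l - 1] = hrows + prev[n];
  }
  // make best monotone in l (a coarser optimum is always admissible)
  for (int l = 1; l < max_cols; ++l)
    if (best[l] < best[l - 1]) best[l] = best[l - 1];
}

double n_choose_k(int n, int k) {
  if (k < 0 || k > n) return 0.0;
  double r = 1.0;
  for (int i = 1; i <= k; ++i) r = r * (n - k + i) / i;
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".best_mi_profile")]]
NumericVector best_mi_profile(NumericVector a, NumericVector b,
                              int nrows, int max_cols,
                              int exact_limit) {
  const int n = a.size();
  if (b.size() != n) stop("profiles must have the same length");
  if (nrows < 1 || max_cols < 1) stop("invalid grid dimensions");
  if (nrows > n) nrows = n;

  std::vector<int> ord_a = stable_order(a);
  std::vector<int> ord_b = stable_order(b);
  std::vector<double> best(max_cols, 0.0);
  std::vector<int> rows(n, 0);

  const double ncomb = n_choose_k(n - 1, nrows - 1);
  if (nrows == 1) {
    dp_columns(ord_a, rows, 1, max_cols, best);
  } else if (ncomb <= (double)exact_limit) {
    // exact: enumerate all placements of nrows-1 cuts in the n-1 gaps of
    // the row-axis rank order
    std::vector<int> cut(nrows - 1);
    for (int k = 0; k < nrows - 1; ++k) cut[k] = k + 1;  // cut after pos
    for (;;) {
      int r = 0, next = 0;
      for (int p = 0; p < n; ++p) {
        while (next < nrows - 1 && p >= cut[next]) { ++r; ++next; }
        rows[ord_b[p]] = r;
      }
      dp_columns(ord_a, rows, nrows, max_cols, best);
      // next combination of cut positions (values in 1..n-1, increasing)
      int k = nrows - 2;
      while (k >= 0 && cut[k] == n - 1 - (nrows - 2 - k)) --k;
      if (k < 0) break;
      ++cut[k];
      for (int j = k + 1; j < nrows - 1; ++j) cut[j] = cut[j - 1] + 1;
    }
  } else {
    // rank equipartition of the row axis (ties broken by original order)
    for (int p = 0; p < n; ++p)
      rows[ord_b[p]] = (int)(((long long)p * nrows) / n);
    dp_columns(ord_a, rows, nrows, max_cols, best);
  }
  return wrap(best);
}
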