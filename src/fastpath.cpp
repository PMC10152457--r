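#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Average ranks (ties share the mean rank), Mann-Whitney convention.
static void avg_ranks(const std::vector<double>& v, std::vector<double>& ranks) {
  const int n = (int)v.size();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return v[a] < v[b]; });
  ranks.assign(n, 0.0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    const double r = 0.5 * (i + j) + 1.0;  // 1-based average rank
    for (int k = i; k <= j; ++k) ranks[ord[k]] = r;
    i = j + 1;
  }
}

//' @title All-pairs oriented AUC scan (internal)
//' @description For every ordered wavenumber pair (num, den), num != den,
//'   computes the oriented one-vs-rest AUC of the absorbance ratio for each
//'   class. Ratios with |denominator| < eps are excluded (the metric abstains
//'   on those spectra). Orientation: max(auc, 1 - auc). Classes with no
//'   positive or no negative defined ratio give NA.
//' @param X numeric matrix, spectra in rows, analysis channels in columns
//' @param cls integer class codes 1..K, one per row of X
//' @param K number of classes
//' @param eps denominator guard on the (normalised) absorbance scale
//' @return numeric matrix with p*(p-1) rows (num-major ordered pair order)
//'   and K columns of oriented AUC values
//' @keywords internal
// [[Rcpp::export(name = ".all_pairs_auc")]]
NumericMatrix all_pairs_auc(NumericMatrix X, IntegerVector cls, int K, double eps) {
  const int n = X.nrow(), p = X.ncol();
  const int npairs = p * (p - 1);
  NumericMatrix out(npairs, K);
  std::fill(out.begin(), out.end(), NA_REAL);

  std::vector<double> r, ranks;
  std::vector<int> rcls;
  r.reserve(n);
  rcls.reserve(n);
  std::vector<double> possum(K);
  std::vector<int> poscnt(K);

  int row = 0;
  for (int num = 0; num < p; ++num) {
    for (int den = 0; den < p; ++den) {
      if (den == num) continue;
      r.clear();
      rcls.clear();
      for (int s = 0; s < n; ++s) {
        const double d = X(s, den);
        if (std::fabs(d) >= eps) {
          r.push_back(X(s, num) / d);
          rcls.push_back(cls[s] - 1);
        }
      }
      const int m = (int)r.size();
      if (m >= 2) {
        avg_ranks(r, ranks);
        std::fill(possum.begin(), possum.end(), 0.0);
        std::fill(poscnt.begin(), poscnt.end(), 0);
        for (int s = 0; s < m; ++s) {
          possum[rcls[s]] += ranks[s];
          poscnt[rcls[s]] += 1;
        }
        for (int c = 0; c < K; ++c) {
          const int np = poscnt[c], nn = m - poscnt[c];
          if (np > 0 && nn > 0) {
            const double U = possum[c] - 0.5 * (double)np * (np + 1.0);
            const double a = U / ((double)np * (double)nn);
            out(row, c) = std::max(a, 1.0 - a);
          }
        }
      }
      ++row;
    }
  }
  return out;
}

//' @title Lower convex minorant of a spectrum (internal)
//' @description Computes the greatest convex minorant (lower convex hull
//'   boundary) of the points (x, y), linearly interpolated between hull
//'   vertices; x must be strictly increasing. Hull vertices (including both
//'   endpoints) take their input values exactly.
//' @param x strictly increasing abscissae (wavenumbers)
//' @param y ordinates (absorbances)
//' @return numeric vector: the baseline, same length as x
//' @keywords internal
// [[Rcpp::export(name = ".lower_convex_minorant")]]
NumericVector lower_convex_minorant(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n != y.size()) stop("x and y lengths differ");
  if (n < 3) stop("need at least 3 channels");
  // Andrew monotone chain, lower hull only (x already sorted increasing).
  std::vector<int> hull;
  hull.reserve(n);
  for (int i = 0; i < n; ++i) {
    while (hull.size() >= 2) {
      const int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      const double cross = (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]);
      if (cross <= 0)  // b is above or on the chord a->i: drop it
        hull.pop_back();
      else
        break;
    }
    hull.push_back(i);
  }
  NumericVector base(n);
  for (size_t v = 0; v + 1 < hull.size(); ++v) {
    const int a = hull[v], b = hull[v + 1];
    base[a] = y[a];
    for (int k = a + 1; k < b; ++k)
      base[k] = y[a] + (y[b] - y[a]) * (x[k] - x[a]) / (x[b] - x[a]);
    base[b] = y[b];
  }
  return base;
}
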