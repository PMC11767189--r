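#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Fenwick (binary indexed) tree accumulating four running sums keyed by
// y-rank: pair count, sum of x, sum of y, sum of x*y. Supports prefix
// queries in O(log n).
struct Fenwick4 {
  int n;
  std::vector<double> cnt, sx, sy, sxy;
  explicit Fenwick4(int n_) : n(n_), cnt(n_ + 1, 0.0), sx(n_ + 1, 0.0),
                              sy(n_ + 1, 0.0), sxy(n_ + 1, 0.0) {}
  void add(int i, double x, double y) {
    for (; i <= n; i += i & (-i)) {
      cnt[i] += 1.0; sx[i] += x; sy[i] += y; sxy[i] += x * y;
    }
  }
  // prefix sums over ranks 1..i
  void query(int i, double out[4]) const {
    out[0] = out[1] = out[2] = out[3] = 0.0;
    for (; i > 0; i -= i & (-i)) {
      out[0] += cnt[i]; out[1] += sx[i]; out[2] += sy[i]; out[3] += sxy[i];
    }
  }
};

// Row sums of the pairwise absolute-difference matrix, aligned to the
// original ordering: a_i = sum_j |v_i - v_j|, in O(n log n).
static std::vector<double> abs_row_sums(const NumericVector &v) {
  const int n = v.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  std::vector<double> out(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += v[i];
  double prefix = 0.0;
  for (int k = 0; k < n; ++k) {
    const double vi = v[ord[k]];
    prefix += vi;
    // sum_{j<=k} (vi - v_(j)) + sum_{j>k} (v_(j) - vi), 1-based rank k+1
    out[ord[k]] = (2.0 * (k + 1) - n) * vi - 2.0 * prefix + total;
  }
  return out;
}

// Squared empirical (V-statistic) distance covariance of two univariate
// samples in O(n log n):
//   Vn^2 = T1/n^2 - 2*S2/n^3 + T3*T4/n^4
// with T1 = sum_ij |xi-xj||yi-yj|, S2 = sum_i a_i b_i (a, b the distance
// row sums), T3 = sum a_i, T4 = sum b_i. T1 is computed by sorting on x
// and sweeping a Fenwick tree over y-ranks; pairs tied in y contribute
// zero to T1 regardless of which sign branch they land in, so ties need
// no special casing.
// [[Rcpp::export]]
double dcov2_fast_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  if (n < 2) stop("need at least 2 observations");

  // dense ranks of y (ties share a rank)
  std::vector<double> ys(y.begin(), y.end());
  std::sort(ys.begin(), ys.end());
  ys.erase(std::unique(ys.begin(), ys.end()), ys.end());
  const int m = (int)ys.size();
  std::vector<int> yrank(n);
  for (int i = 0; i < n; ++i)
    yrank[i] = 1 + (int)(std::lower_bound(ys.begin(), ys.end(), y[i]) - ys.begin());

  // process in x order (ties in x contribute zero, order irrelevant)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  Fenwick4 bit(m);
  double T1half = 0.0;
  double Csum = 0.0, Xsum = 0.0, Ysum = 0.0, XYsum = 0.0;  // totals inserted
  double q[4];
  for (int k = 0; k < n; ++k) {
    const int j = ord[k];
    const double xj = x[j], yj = y[j];
    bit.query(yrank[j], q);  // i earlier in x-order with y_i <= y_j
    const double cle = q[0], sxle = q[1], syle = q[2], sxyle = q[3];
    const double cgt = Csum - cle, sxgt = Xsum - sxle,
                 sygt = Ysum - syle, sxygt = XYsum - sxyle;
    // y_i <= y_j: (xj - xi)(yj - yi)
    T1half += cle * xj * yj - xj * syle - yj * sxle + sxyle;
    // y_i >  y_j: (xj - xi)(yi - yj)
    T1half += xj * sygt - cgt * xj * yj - sxygt + yj * sxgt;
    bit.add(yrank[j], xj, yj);
    Csum += 1.0; Xsum += xj; Ysum += yj; XYsum += xj * yj;
  }
  const double T1 = 2.0 * T1half;

  std::vector<double> a = abs_row_sums(x), b = abs_row_sums(y);
  double S2 = 0.0, T3 = 0.0, T4 = 0.0;
  for (int i = 0; i < n; ++i) {
    S2 += a[i] * b[i]; T3 += a[i]; T4 += b[i];
  }

  const double dn = (double)n;
  double v2 = T1 / (dn * dn) - 2.0 * S2 / (dn * dn * dn) +
              T3 * T4 / (dn * dn * dn * dn);
  return v2;
}
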