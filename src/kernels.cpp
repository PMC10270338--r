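#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact STOMP-style matrix profile.
//
// x is expected pre-centred (global mean subtracted) by the R wrapper for
// numerical stability; distances are shift-invariant so this changes nothing.
// Rolling means/sds use compensated running sums over the centred series.
// Zero-variance convention: both windows constant -> 0; exactly one -> sqrt(m).
// [[Rcpp::export]]
List stomp_cpp(NumericVector x, int m, int excl) {
  const int n = x.size();
  const int l = n - m + 1;
  const double inf = std::numeric_limits<double>::infinity();

  std::vector<double> mu(l), sig(l);
  std::vector<bool> flat(l);
  {
    long double s = 0.0L, s2 = 0.0L;
    for (int i = 0; i < m; ++i) { s += x[i]; s2 += (long double)x[i] * x[i]; }
    for (int i = 0; i < l; ++i) {
      if (i > 0) {
        s  += x[i + m - 1] - x[i - 1];
        s2 += (long double)x[i + m - 1] * x[i + m - 1]
            - (long double)x[i - 1] * x[i - 1];
      }
      mu[i] = (double)(s / m);
      long double v = s2 / m - (long double)mu[i] * mu[i];
      if (v < 0) v = 0;
      sig[i] = std::sqrt((double)v);
      flat[i] = sig[i] <= 0.0;
    }
  }

  // first row of sliding dot products (doubles as the first column by symmetry)
  std::vector<double> qt(l), qt_first(l), qt_prev(l);
  for (int j = 0; j < l; ++j) {
    double d = 0.0;
    for (int k = 0; k < m; ++k) d += x[k] * x[j + k];
    qt[j] = d;
  }
  qt_first = qt;

  NumericVector mp(l, inf);
  IntegerVector idx(l, NA_INTEGER);
  const double sqm = std::sqrt((double)m);

  for (int i = 0; i < l; ++i) {
    if (i > 0) {
      qt_prev = qt;
      for (int j = l - 1; j >= 1; --j)
        qt[j] = qt_prev[j - 1]
              - x[i - 1] * x[j - 1]
              + x[i + m - 1] * x[j + m - 1];
      qt[0] = qt_first[i];
    }
    double best = inf;
    int best_j = -1;
    for (int j = 0; j < l; ++j) {
      if (std::abs(i - j) <= excl) continue;
      double d;
      if (flat[i] && flat[j]) {
        d = 0.0;
      } else if (flat[i] || flat[j]) {
        d = sqm;
      } else {
        double corr = (qt[j] - m * mu[i] * mu[j]) / (m * sig[i] * sig[j]);
        if (corr > 1.0) corr = 1.0;
        if (corr < -1.0) corr = -1.0;
        d = std::sqrt(2.0 * m * (1.0 - corr));
      }
      if (d < best) { best = d; best_j = j; }
    }
    mp[i] = best;
    idx[i] = best_j + 1;  // 1-based
  }
  return List::create(_["values"] = mp, _["indices"] = idx);
}

// Dynamic-time-warping DP restricted to a per-row column window [lo_i, hi_i]
// (1-based inclusive bounds, one pair per row of a). Local cost |a_i - b_j|,
// steps {(1,0),(0,1),(1,1)}, ties broken diagonal first, then (i-1,j), then
// (i,j-1). Full DTW is the special case lo_i = 1, hi_i = |b|.
// Returns total cost and the warping path (1-based index pairs).
// [[Rcpp::export]]
List dtw_window_cpp(NumericVector a, NumericVector b,
                    IntegerVector lo, IntegerVector hi) {
  const int n = a.size(), mlen = b.size();
  const double inf = std::numeric_limits<double>::infinity();

  std::vector<int> off(n), width(n);
  std::vector<long long> start(n);
  long long total = 0;
  for (int i = 0; i < n; ++i) {
    off[i] = lo[i] - 1;
    width[i] = hi[i] - lo[i] + 1;
    start[i] = total;
    total += width[i];
  }
  std::vector<double> D((size_t)total, inf);
  std::vector<signed char> bp((size_t)total, -1); // 0=diag,1=up,2=left

  for (int i = 0; i < n; ++i) {
    for (int w = 0; w < width[i]; ++w) {
      int j = off[i] + w;
      double c = std::abs(a[i] - b[j]);
      if (i == 0 && j == 0) { D[start[i]] = c; bp[start[i]] = -1; continue; }
      double dd = inf, du = inf, dl = inf;
      if (i > 0) {
        int pw = j - 1 - off[i - 1];
        if (j > 0 && pw >= 0 && pw < width[i - 1]) dd = D[start[i - 1] + pw];
        int uw = j - off[i - 1];
        if (uw >= 0 && uw < width[i - 1]) du = D[start[i - 1] + uw];
      }
      if (w > 0) dl = D[start[i] + w - 1];
      double best = dd; signed char arg = 0;
      if (du < best) { best = du; arg = 1; }
      if (dl < best) { best = dl; arg = 2; }
      if (best == inf) continue; // unreachable cell
      D[start[i] + w] = best + c;
      bp[start[i] + w] = arg;
    }
  }

  int endw = mlen - 1 - off[n - 1];
  if (endw < 0 || endw >= width[n - 1] || !R_finite(D[start[n - 1] + endw]))
    stop("DTW window does not connect (1,1) to (|a|,|b|)");
  double cost = D[start[n - 1] + endw];

  std::vector<int> pi, pj;
  int i = n - 1, j = mlen - 1;
  while (true) {
    pi.push_back(i + 1); pj.push_back(j + 1);
    signed char s = bp[start[i] + (j - off[i])];
    if (s == -1) break;
    if (s == 0) { --i; --j; }
    else if (s == 1) { --i; }
    else { --j; }
  }
  const int plen = pi.size();
  IntegerVector ri(plen), rj(plen);
  for (int k = 0; k < plen; ++k) { ri[k] = pi[plen - 1 - k]; rj[k] = pj[plen - 1 - k]; }
  return List::create(_["cost"] = cost, _["i"] = ri, _["j"] = rj);
}
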