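#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Extrema scan with plateau handling: a plateau counts once, at its midpoint
// (floor). Only strictly interior extrema are reported (0-based indices).
// Also counts zero crossings (exact zeros dropped from the sign sequence),
// so one pass serves both the envelope construction and the IMF condition.
static void scan_signal(const std::vector<double>& x,
                        std::vector<int>& maxima,
                        std::vector<int>& minima,
                        int& zc) {
  const int n = (int)x.size();
  maxima.clear();
  minima.clear();
  zc = 0;
  int last_sign = 0;
  for (int i = 0; i < n; ++i) {
    const int s = (x[i] > 0) - (x[i] < 0);
    if (s != 0) {
      if (last_sign != 0 && s != last_sign) ++zc;
      last_sign = s;
    }
  }
  if (n < 3) return;
  int i = 1;
  while (i < n - 1) {
    if (x[i] == x[i - 1]) { ++i; continue; }
    int j = i;                       // plateau [i, j] of equal values
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    if (j >= n - 1) break;           // plateau touches the right boundary
    const double prev = x[i - 1], next = x[j + 1];
    const int mid = (i + j) / 2;
    if (x[i] > prev && x[i] > next) maxima.push_back(mid);
    else if (x[i] < prev && x[i] < next) minima.push_back(mid);
    i = j + 1;
  }
}

// workspace reused across sifting iterations to avoid reallocation
struct SplineWork {
  std::vector<double> t, y, h, inv_h, alpha, l, mu, z, m;
};

// Natural cubic spline through (t, y), evaluated at 0..n-1 into out.
// Knot positions are strictly increasing and span [0, n-1].
static void natural_spline_eval(SplineWork& w, int n,
                                std::vector<double>& out) {
  const std::vector<double>& t = w.t;
  const std::vector<double>& y = w.y;
  const int k = (int)t.size();
  if (k == 2) {  // single interval: natural spline degenerates to a line
    const double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = y[0] + slope * (i - t[0]);
    return;
  }
  w.h.resize(k - 1); w.inv_h.resize(k - 1);
  w.alpha.resize(k); w.l.resize(k); w.mu.resize(k); w.z.resize(k);
  w.m.resize(k);
  for (int i = 0; i < k - 1; ++i) {
    w.h[i] = t[i + 1] - t[i];
    w.inv_h[i] = 1.0 / w.h[i];
  }
  // second derivatives m[0..k-1], natural BC m[0]=m[k-1]=0 (Thomas algorithm)
  w.l[0] = 1.0; w.mu[0] = 0.0; w.z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    w.alpha[i] = 3.0 * ((y[i + 1] - y[i]) * w.inv_h[i] -
                        (y[i] - y[i - 1]) * w.inv_h[i - 1]);
    const double li = 2.0 * (t[i + 1] - t[i - 1]) - w.h[i - 1] * w.mu[i - 1];
    const double inv_li = 1.0 / li;
    w.mu[i] = w.h[i] * inv_li;
    w.z[i] = (w.alpha[i] - w.h[i - 1] * w.z[i - 1]) * inv_li;
  }
  w.m[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) w.m[i] = w.z[i] - w.mu[i] * w.m[i + 1];

  int seg = 0;
  for (int i = 0; i < n; ++i) {
    const double xv = (double)i;
    while (seg < k - 2 && t[seg + 1] < xv) ++seg;
    const double inv_dt = w.inv_h[seg];
    const double dt2_6 = w.h[seg] * w.h[seg] / 6.0;
    const double a = (t[seg + 1] - xv) * inv_dt, b = (xv - t[seg]) * inv_dt;
    out[i] = a * y[seg] + b * y[seg + 1] +
      ((a * a * a - a) * w.m[seg] + (b * b * b - b) * w.m[seg + 1]) * dt2_6;
  }
}

// Mirror the two extrema nearest each end about the end samples (0 and n-1),
// then fit the envelope spline through the extended knot set.
static void envelope(SplineWork& w, const std::vector<double>& x,
                     const std::vector<int>& idx, int n,
                     std::vector<double>& env) {
  const int p = (int)idx.size();
  w.t.clear(); w.y.clear();
  w.t.push_back(-(double)idx[1]);        w.y.push_back(x[idx[1]]);
  w.t.push_back(-(double)idx[0]);        w.y.push_back(x[idx[0]]);
  for (int i = 0; i < p; ++i) { w.t.push_back((double)idx[i]); w.y.push_back(x[idx[i]]); }
  const double R = 2.0 * (n - 1);
  w.t.push_back(R - (double)idx[p - 1]); w.y.push_back(x[idx[p - 1]]);
  w.t.push_back(R - (double)idx[p - 2]); w.y.push_back(x[idx[p - 2]]);
  natural_spline_eval(w, n, env);
}

struct SiftWork {
  SplineWork spline;
  std::vector<double> q, qn, eu, el;
  std::vector<int> mx, mn;
};

// status: 0 = IMF accepted, 1 = monotonic input (no IMF extractable).
// Stops when the energy-normalised sum of difference between successive
// iterates, sum|q_{k-1}-q_k|^2 / sum q_{k-1}^2, falls below `threshold` and
// the iterate satisfies the IMF condition (|#extrema - #zc| <= 1), or after
// max_iter iterations; at the cap the most recent condition-satisfying
// iterate is the one accepted.
static int sift_core(SiftWork& w, const std::vector<double>& x,
                     double threshold, int max_iter, double guard,
                     std::vector<double>& imf) {
  const int n = (int)x.size();
  w.q = x;
  w.qn.resize(n);
  w.eu.resize(n);
  w.el.resize(n);
  std::vector<double> last_ok;
  int zc;
  scan_signal(w.q, w.mx, w.mn, zc);
  for (int iter = 0; iter < max_iter; ++iter) {
    if ((int)w.mx.size() < 2 || (int)w.mn.size() < 2) {
      if (iter == 0) return 1;
      break;  // residual became (near-)monotonic mid-sift: accept current q
    }
    envelope(w.spline, w.q, w.mx, n, w.eu);
    envelope(w.spline, w.q, w.mn, n, w.el);
    // fused: subtract the envelope mean and accumulate the stop criterion
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      const double qi = w.q[i];
      const double qni = qi - 0.5 * (w.eu[i] + w.el[i]);
      w.qn[i] = qni;
      const double diff = qi - qni;
      num += diff * diff;
      den += qi * qi;
    }
    const double sd = (den >= guard) ? num / den : R_PosInf;
    w.q.swap(w.qn);
    scan_signal(w.q, w.mx, w.mn, zc);
    const bool imf_ok =
      std::abs((int)(w.mx.size() + w.mn.size()) - zc) <= 1;
    if (imf_ok) last_ok = w.q;
    if (sd < threshold && imf_ok) break;
  }
  imf = last_ok.empty() ? w.q : last_ok;
  return 0;
}

// [[Rcpp::export(name = ".emd_sift_cpp")]]
List emd_sift_cpp(NumericVector x, double threshold, int max_iter,
                  double guard) {
  SiftWork w;
  std::vector<double> xv(x.begin(), x.end()), imf;
  const int status = sift_core(w, xv, threshold, max_iter, guard, imf);
  if (status != 0)
    return List::create(_["status"] = status);
  NumericVector imf_r(imf.begin(), imf.end());
  NumericVector res(x.size());
  for (int i = 0; i < x.size(); ++i) res[i] = x[i] - imf_r[i];
  return List::create(_["status"] = 0, _["imf"] = imf_r, _["residual"] = res);
}

// [[Rcpp::export(name = ".emd_decompose_cpp")]]
List emd_decompose_cpp(NumericVector x, double threshold, int max_iter,
                       int max_imfs, double guard) {
  const int n = x.size();
  SiftWork w;
  std::vector<double> res(x.begin(), x.end()), imf;
  std::vector<std::vector<double> > imfs;
  std::vector<int> mx, mn;
  int zc;
  while ((int)imfs.size() < max_imfs) {
    scan_signal(res, mx, mn, zc);
    if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
    if (sift_core(w, res, threshold, max_iter, guard, imf) != 0) break;
    imfs.push_back(imf);
    for (int i = 0; i < n; ++i) res[i] -= imf[i];
  }
  NumericMatrix M(n, (int)imfs.size());
  for (int j = 0; j < (int)imfs.size(); ++j)
    for (int i = 0; i < n; ++i) M(i, j) = imfs[j][i];
  NumericVector residue(res.begin(), res.end());
  return List::create(_["imfs"] = M, _["residue"] = residue);
}

// [[Rcpp::export(name = ".find_extrema_cpp")]]
List find_extrema_cpp(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> mx, mn;
  int zc;
  scan_signal(xv, mx, mn, zc);
  IntegerVector maxima(mx.size()), minima(mn.size());
  for (size_t i = 0; i < mx.size(); ++i) maxima[i] = mx[i] + 1;  // 1-based
  for (size_t i = 0; i < mn.size(); ++i) minima[i] = mn[i] + 1;
  return List::create(_["maxima"] = maxima, _["minima"] = minima);
}

// [[Rcpp::export(name = ".zero_crossings_cpp")]]
int zero_crossings_cpp(NumericVector x) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> mx, mn;
  int zc;
  scan_signal(xv, mx, mn, zc);
  return zc;
}
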