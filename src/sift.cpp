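#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local extrema by 3-point comparison; on a plateau the first sample
// wins (matches local_extrema() on the R side).
static void find_extrema(const double* x, int n,
                         std::vector<double>& mx, std::vector<double>& mn) {
  int p = 0;      // last nonzero slope sign
  int pidx = -1;  // slope index where it was seen
  for (int i = 0; i < n - 1; ++i) {
    double d = x[i + 1] - x[i];
    int s = (d > 0) - (d < 0);
    if (s == 0) continue;
    if (p > 0 && s < 0) mx.push_back(pidx + 2);   // 1-based sample index
    if (p < 0 && s > 0) mn.push_back(pidx + 2);
    p = s;
    pidx = i;
  }
}

// Natural cubic spline through (xi, yi) evaluated at 1..n into out.
// xi strictly increasing (duplicates removed by the caller).
static void spline_eval(const std::vector<double>& xi,
                        const std::vector<double>& yi,
                        int n, std::vector<double>& out) {
  const int m = (int)xi.size();
  if (m == 2) {
    double a = (yi[1] - yi[0]) / (xi[1] - xi[0]);
    for (int t = 0; t < n; ++t) out[t] = yi[0] + a * ((t + 1) - xi[0]);
    return;
  }
  std::vector<double> h(m - 1), mu(m), z(m), c(m, 0.0);
  for (int i = 0; i < m - 1; ++i) h[i] = xi[i + 1] - xi[i];
  mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    double alpha = 3.0 * (yi[i + 1] - yi[i]) / h[i]
                 - 3.0 * (yi[i] - yi[i - 1]) / h[i - 1];
    double l = 2.0 * (xi[i + 1] - xi[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l;
    z[i] = (alpha - h[i - 1] * z[i - 1]) / l;
  }
  c[m - 1] = 0.0;
  for (int j = m - 2; j >= 0; --j) c[j] = z[j] - mu[j] * c[j + 1];
  int seg = 0;
  double b = 0, d = 0, x0 = 0, y0 = 0;
  bool fresh = true;
  for (int t = 0; t < n; ++t) {
    double x = t + 1;
    while (seg < m - 2 && x > xi[seg + 1]) { ++seg; fresh = true; }
    if (fresh) {
      b = (yi[seg + 1] - yi[seg]) / h[seg]
        - h[seg] * (c[seg + 1] + 2.0 * c[seg]) / 3.0;
      d = (c[seg + 1] - c[seg]) / (3.0 * h[seg]);
      x0 = xi[seg];
      y0 = yi[seg];
      fresh = false;
    }
    double dx = x - x0;
    out[t] = y0 + dx * (b + dx * (c[seg] + dx * d));
  }
}

// assemble mirrored knots (two outermost extrema reflected about each
// boundary sample), drop duplicate positions, fit/evaluate the envelope
static void envelope(const double* x, const std::vector<double>& ei,
                     int n, std::vector<double>& out) {
  const int k = (int)ei.size();
  const int nl = k < 2 ? k : 2, nr = k < 2 ? k : 2;
  std::vector<double> xi, yi;
  xi.reserve(k + 4); yi.reserve(k + 4);
  for (int i = nl - 1; i >= 0; --i) {
    xi.push_back(2.0 - ei[i]);
    yi.push_back(x[(int)ei[i] - 1]);
  }
  for (int i = 0; i < k; ++i) {
    xi.push_back(ei[i]);
    yi.push_back(x[(int)ei[i] - 1]);
  }
  for (int i = k - 1; i >= k - nr; --i) {
    xi.push_back(2.0 * n - ei[i]);
    yi.push_back(x[(int)ei[i] - 1]);
  }
  std::vector<double> xs, ys;
  xs.reserve(xi.size()); ys.reserve(xi.size());
  for (size_t i = 0; i < xi.size(); ++i) {
    if (i == 0 || xi[i] > xs.back()) {
      xs.push_back(xi[i]);
      ys.push_back(yi[i]);
    }
  }
  spline_eval(xs, ys, n, out);
}

// Extract one IMF by iterated sifting. method: 0 = Rilling envelope
// criterion (|m|/a < 0.05 on 95% of samples, < 0.5 everywhere),
// 1 = Cauchy energy criterion (sum(m^2)/sum(h^2) < stop_sd).
// A sift iteration that triples the mode RMS is treated as divergent
// (spline overshoot through sparse extrema) and sifting stops on the
// last stable iterate. Returns NULL when the input has fewer than two
// maxima or two minima.
// [[Rcpp::export(name = ".sift_imf")]]
SEXP sift_imf(NumericVector x, int method, double stop_sd, int max_sift) {
  const int n = x.size();
  NumericVector h = clone(x);
  double* ph = REAL(h);
  double rms0 = 0.0;
  for (int t = 0; t < n; ++t) rms0 += ph[t] * ph[t];
  rms0 = std::sqrt(rms0 / n);
  std::vector<double> mx, mn, up(n), lo(n);
  mx.reserve(n / 8 + 8);
  mn.reserve(n / 8 + 8);
  const double eps = 2.220446e-16;
  int iters = 0;
  for (int it = 0; it < max_sift; ++it) {
    ++iters;
    mx.clear();
    mn.clear();
    find_extrema(ph, n, mx, mn);
    if (mx.size() < 2 || mn.size() < 2) {
      if (it == 0) return R_NilValue;
      break;
    }
    envelope(ph, mx, n, up);
    envelope(ph, mn, n, lo);
    double sum_m2 = 0.0, sum_h2 = 0.0, rms_new = 0.0;
    int n_big = 0;
    double max_sig = 0.0;
    for (int t = 0; t < n; ++t) {
      double m = 0.5 * (up[t] + lo[t]);
      double a = 0.5 * (up[t] - lo[t]);
      double sig = std::fabs(m) / (a > eps ? a : eps);
      if (sig > 0.05) ++n_big;
      if (sig > max_sig) max_sig = sig;
      sum_m2 += m * m;
      sum_h2 += ph[t] * ph[t];
      double hn = ph[t] - m;
      rms_new += hn * hn;
      lo[t] = hn;               // reuse lo as h_new scratch
    }
    rms_new = std::sqrt(rms_new / n);
    if (rms_new > 3.0 * rms0) break;          // divergence guard
    bool done = (method == 0)
      ? ((double)n_big / n < 0.05 && max_sig < 0.5)
      : (sum_m2 / (sum_h2 > eps ? sum_h2 : eps) < stop_sd);
    for (int t = 0; t < n; ++t) ph[t] = lo[t];
    if (done) break;
  }
  h.attr("iters") = iters;
  return h;
}
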