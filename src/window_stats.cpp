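#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Ten statistics per window over x[lo..hi] (1-based, inclusive) for each
// window.  Column order: mean, min, max, median, maxamp, var, sd, absdev,
// kurtosis, skewness.  Population moments, Fisher excess kurtosis;
// zero-variance windows get skewness = kurtosis = 0.  Consecutive windows
// with identical index ranges (low-rate signals under a sub-sample step)
// reuse the previous row.
// [[Rcpp::export]]
NumericMatrix window_stats_cpp(NumericVector x, IntegerVector lo,
                               IntegerVector hi) {
  int nw = lo.size();
  if (hi.size() != nw) stop("lo/hi length mismatch");
  NumericMatrix out(nw, 10);
  std::vector<double> buf;
  for (int w = 0; w < nw; ++w) {
    int a = lo[w] - 1, b = hi[w] - 1;
    if (a < 0 || b >= x.size() || b < a) stop("window index out of range");
    if (w > 0 && lo[w] == lo[w - 1] && hi[w] == hi[w - 1]) {
      for (int j = 0; j < 10; ++j) out(w, j) = out(w - 1, j);
      continue;
    }
    int n = b - a + 1;
    double s = 0.0, mn = x[a], mx = x[a], ma = 0.0;
    for (int i = a; i <= b; ++i) {
      double v = x[i];
      s += v;
      if (v < mn) mn = v;
      if (v > mx) mx = v;
      double av = std::fabs(v);
      if (av > ma) ma = av;
    }
    double mean = s / n;
    double m2 = 0.0, m3 = 0.0, m4 = 0.0, ad = 0.0;
    for (int i = a; i <= b; ++i) {
      double d = x[i] - mean, d2 = d * d;
      m2 += d2;
      m3 += d2 * d;
      m4 += d2 * d2;
      ad += std::fabs(d);
    }
    m2 /= n; m3 /= n; m4 /= n; ad /= n;
    buf.assign(x.begin() + a, x.begin() + b + 1);
    int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (n % 2 == 0) {
      med = (med + *std::max_element(buf.begin(), buf.begin() + h)) / 2.0;
    }
    double sdev = std::sqrt(m2);
    double skw = 0.0, kur = 0.0;
    if (m2 > 0.0) {
      skw = m3 / (sdev * sdev * sdev);
      kur = m4 / (m2 * m2) - 3.0;
    }
    out(w, 0) = mean; out(w, 1) = mn;  out(w, 2) = mx;
    out(w, 3) = med;  out(w, 4) = ma;  out(w, 5) = m2;
    out(w, 6) = sdev; out(w, 7) = ad;  out(w, 8) = kur;
    out(w, 9) = skw;
  }
  return out;
}
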