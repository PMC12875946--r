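#include <Rcpp.h>
using namespace Rcpp;

// One analysis step of a periodized orthonormal two-channel filter bank:
//   a[k] = sum_m h[m] x[(2k+m) mod n],  d[k] = sum_m g[m] x[(2k+m) mod n].
// With h the orthonormal scaling filter and g its quadrature mirror, the map
// x -> (a, d) is an orthogonal transform for any even n (the periodized
// autocorrelation of an orthonormal filter vanishes at even non-zero lags),
// so the synthesis step below - its transpose - inverts it exactly.
// [[Rcpp::export(name = ".wpt_analysis_step_cpp")]]
List wpt_analysis_step_cpp(NumericVector x, NumericVector h, NumericVector g) {
  const int n = x.size(), L = h.size(), half = n / 2;
  if (n % 2 != 0) stop("wpt: node length must be even");
  NumericVector a(half), d(half);
  for (int k = 0; k < half; ++k) {
    double sa = 0.0, sd = 0.0;
    int idx = (2 * k) % n;
    for (int m = 0; m < L; ++m) {
      const double v = x[idx];
      sa += h[m] * v;
      sd += g[m] * v;
      if (++idx == n) idx = 0;
    }
    a[k] = sa;
    d[k] = sd;
  }
  return List::create(_["a"] = a, _["d"] = d);
}

// Transpose of the analysis step: x[(2k+m) mod n] += h[m] a[k] + g[m] d[k].
// [[Rcpp::export(name = ".wpt_synthesis_step_cpp")]]
NumericVector wpt_synthesis_step_cpp(NumericVector a, NumericVector d,
                                     NumericVector h, NumericVector g) {
  const int half = a.size(), n = 2 * half, L = h.size();
  NumericVector x(n);
  for (int k = 0; k < half; ++k) {
    const double ak = a[k], dk = d[k];
    int idx = (2 * k) % n;
    for (int m = 0; m < L; ++m) {
      x[idx] += h[m] * ak + g[m] * dk;
      if (++idx == n) idx = 0;
    }
  }
  return x;
}
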