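#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic time warping with absolute-difference local cost and the
// symmetric step pattern (diagonal, up, left). Rolling two-row dynamic
// program, O(n*m) time, O(m) memory. When `normalize_path` is true the
// accumulated cost is divided by the number of steps on the optimal path,
// which requires carrying a parallel step-count table.
// [[Rcpp::export(name = ".dtw_distance_cpp")]]
double dtw_distance_cpp(NumericVector x, NumericVector y, bool normalize_path) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("dtw_distance: empty input");
  const double *px = REAL(x), *py = REAL(y);
  std::vector<double> row_a(m), row_b(m);
  double *prev = row_a.data(), *curr = row_b.data();

  if (!normalize_path) {
    prev[0] = std::fabs(px[0] - py[0]);
    for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(px[0] - py[j]);
    for (int i = 1; i < n; ++i) {
      const double xi = px[i];
      curr[0] = prev[0] + std::fabs(xi - py[0]);
      double left = curr[0];
      for (int j = 1; j < m; ++j) {
        const double diag = prev[j - 1], up = prev[j];
        double best = diag < up ? diag : up;
        if (left < best) best = left;
        left = best + std::fabs(xi - py[j]);
        curr[j] = left;
      }
      std::swap(prev, curr);
    }
    return prev[m - 1];
  }

  std::vector<double> len_a(m), len_b(m);
  double *plen = len_a.data(), *clen = len_b.data();
  prev[0] = std::fabs(px[0] - py[0]);
  plen[0] = 1.0;
  for (int j = 1; j < m; ++j) {
    prev[j] = prev[j - 1] + std::fabs(px[0] - py[j]);
    plen[j] = plen[j - 1] + 1.0;
  }
  for (int i = 1; i < n; ++i) {
    const double xi = px[i];
    curr[0] = prev[0] + std::fabs(xi - py[0]);
    clen[0] = plen[0] + 1.0;
    for (int j = 1; j < m; ++j) {
      const double c = std::fabs(xi - py[j]);
      double best = prev[j - 1], len = plen[j - 1];
      if (prev[j] < best) { best = prev[j]; len = plen[j]; }
      if (curr[j - 1] < best) { best = curr[j - 1]; len = clen[j - 1]; }
      curr[j] = best + c;
      clen[j] = len + 1.0;
    }
    std::swap(prev, curr);
    std::swap(plen, clen);
  }
  return prev[m - 1] / plen[m - 1];
}
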