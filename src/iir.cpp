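#include <Rcpp.h>
using namespace Rcpp;

// Causal IIR filter y = filter(b, a, x) applied to each column of x
// (direct form II transposed, a[0] assumed 1).  Used by the zero-phase
// Butterworth wrapper and the band-limited noise generator; the recursion
// cannot be vectorized in R.
// [[Rcpp::export]]
NumericMatrix iir_filter_mat(NumericVector b, NumericVector a,
                             NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  NumericMatrix y(n, p);
  std::vector<double> z(ns);
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  const double *xp = REAL(x);
  double *yp = REAL(y);
  for (int j = 0; j < p; ++j) {
    const double *xc = xp + static_cast<size_t>(j) * n;
    double *yc = yp + static_cast<size_t>(j) * n;
    std::fill(z.begin(), z.end(), 0.0);
    for (int t = 0; t < n; ++t) {
      const double xt = xc[t];
      const double yt = bb[0] * xt + z[0];
      for (int k = 0; k < ns - 1; ++k) {
        z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
      }
      z[ns - 1] = bb[ns] * xt - aa[ns] * yt;
      yc[t] = yt;
    }
  }
  return y;
}
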