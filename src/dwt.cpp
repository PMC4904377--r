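#include <Rcpp.h>
using namespace Rcpp;

// One periodic analysis step down the columns of m: for output row k
// (0-based, n/2 rows), a[k] = sum_j lo[j] m[(2k + j) mod n], likewise hi.
// Returns rbind(approx, detail).
// [[Rcpp::export]]
NumericMatrix cpp_dwt_cols(NumericMatrix m, NumericVector lo, NumericVector hi) {
  const int n = m.nrow(), nc = m.ncol(), L = lo.size(), nh = n / 2;
  NumericMatrix out(n, nc);
  const double *mp = m.begin();
  double *op = out.begin();
  for (int col = 0; col < nc; ++col) {
    const double *x = mp + (std::size_t)col * n;
    double *oa = op + (std::size_t)col * n;
    double *od = oa + nh;
    for (int k = 0; k < nh; ++k) {
      double a = 0.0, d = 0.0;
      int pos = 2 * k;
      for (int j = 0; j < L; ++j) {
        const double v = x[pos];
        a += lo[j] * v;
        d += hi[j] * v;
        if (++pos == n) pos = 0;
      }
      oa[k] = a;
      od[k] = d;
    }
  }
  return out;
}

// Exact transpose of cpp_dwt_cols (= inverse for an orthonormal bank):
// scatters approx/detail back through the same index pattern.
// [[Rcpp::export]]
NumericMatrix cpp_idwt_cols(NumericMatrix ad, NumericVector lo, NumericVector hi) {
  const int n = ad.nrow(), nc = ad.ncol(), L = lo.size(), nh = n / 2;
  NumericMatrix out(n, nc);
  const double *ap = ad.begin();
  double *op = out.begin();
  for (int col = 0; col < nc; ++col) {
    const double *oa = ap + (std::size_t)col * n;
    const double *od = oa + nh;
    double *x = op + (std::size_t)col * n;
    for (int k = 0; k < nh; ++k) {
      const double a = oa[k], d = od[k];
      int pos = 2 * k;
      for (int j = 0; j < L; ++j) {
        x[pos] += lo[j] * a + hi[j] * d;
        if (++pos == n) pos = 0;
      }
    }
  }
  return out;
}
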