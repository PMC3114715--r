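// Single-pass linear interpolation helpers for the signal simulator: avoid
// the large temporaries R-level row-gather arithmetic would allocate.

#include <Rcpp.h>
using namespace Rcpp;

static void rms_normalize(NumericMatrix& M) {
  const int n = M.nrow(), k = M.ncol();
  for (int j = 0; j < k; ++j) {
    double* o = &M(0, j);
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += o[i] * o[i];
    const double s = std::sqrt(ss / n);
    if (s > 0) for (int i = 0; i < n; ++i) o[i] /= s;
  }
}

// out[i, j] = M[i1[i], j] * (1 - w[i]) + M[i1[i] + 1, j] * w[i]
// i1 is 1-based. With normalize = TRUE each output column is scaled to unit
// root-mean-square.
// [[Rcpp::export(name = ".lerpRowsCpp")]]
NumericMatrix lerpRowsCpp(const NumericMatrix& M, const IntegerVector& i1,
                          const NumericVector& w, bool normalize = false) {
  const int n = i1.size(), k = M.ncol();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    const double* col = &M(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const int r = i1[i] - 1;
      o[i] = col[r] * (1.0 - w[i]) + col[r + 1] * w[i];
    }
  }
  if (normalize) rms_normalize(out);
  return out;
}

// Interpolate a complex lowpass envelope (Er + i Ei, coarse grid) to the
// full rate and mix it onto a carrier:
// out[i, j] = lerp(Er)[i, j] * cosph[i] - lerp(Ei)[i, j] * sinph[i]
// [[Rcpp::export(name = ".alphaMixCpp")]]
NumericMatrix alphaMixCpp(const NumericMatrix& Er, const NumericMatrix& Ei,
                          const IntegerVector& i1, const NumericVector& w,
                          const NumericVector& cosph,
                          const NumericVector& sinph,
                          bool normalize = false) {
  const int n = i1.size(), k = Er.ncol();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    const double* er = &Er(0, j);
    const double* ei = &Ei(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const int r = i1[i] - 1;
      const double a = er[r] * (1.0 - w[i]) + er[r + 1] * w[i];
      const double b = ei[r] * (1.0 - w[i]) + ei[r + 1] * w[i];
      o[i] = a * cosph[i] - b * sinph[i];
    }
  }
  if (normalize) rms_normalize(out);
  return out;
}
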