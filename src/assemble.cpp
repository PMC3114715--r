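// Fused assembly of the simulated signal: combines white noise, pink
// background, the envelope-modulated alpha process and the cue transient in
// one pass, writing the result channel-major (channels x samples) so no
// large temporaries or transposes are needed.

#include <Rcpp.h>
using namespace Rcpp;

// Task session block. W, P, A are samples x channels (standard-normal white
// noise, unit-variance pink noise, unit-variance alpha process). The sample
// axis is nTrials slots of S samples. For sample i = trial * S + s:
//   out(j, i) = noiseSd W + bgSd P
//             + ampAlpha[j] * A * (base[s] + ramp[s] * LG(j, dir[trial]-1))
//             + transAmp[j] * trans[s]
// [[Rcpp::export(name = ".assembleSessionCpp")]]
NumericMatrix assembleSessionCpp(const NumericMatrix& W,
                                 const NumericMatrix& P,
                                 const NumericMatrix& A,
                                 double noiseSd, double bgSd,
                                 const NumericVector& base,
                                 const NumericVector& ramp,
                                 const NumericVector& trans,
                                 const NumericVector& transAmp,
                                 const NumericVector& ampAlpha,
                                 const NumericMatrix& LG,
                                 const IntegerVector& dirTrial) {
  const int n = W.nrow(), k = W.ncol(), S = base.size();
  NumericMatrix out(k, n);
  for (int j = 0; j < k; ++j) {
    const double* w = &W(0, j);
    const double* p = &P(0, j);
    const double* a = &A(0, j);
    const double amp = ampAlpha[j], ta = transAmp[j];
    const double* lg = &LG(j, 0);      // row j, stride = k
    for (int i = 0; i < n; ++i) {
      const int s = i % S, trial = i / S;
      const double env = base[s] + ramp[s] * lg[(dirTrial[trial] - 1) * k];
      out(j, i) = noiseSd * w[i] + bgSd * p[i] + amp * a[i] * env +
                  ta * trans[s];
    }
  }
  return out;
}

// Resting block: envelope is a per-sample modulation shared by all channels.
// [[Rcpp::export(name = ".assembleRestingCpp")]]
NumericMatrix assembleRestingCpp(const NumericMatrix& W,
                                 const NumericMatrix& P,
                                 const NumericMatrix& A,
                                 double noiseSd, double bgSd,
                                 const NumericVector& mod,
                                 const NumericVector& ampAlpha) {
  const int n = W.nrow(), k = W.ncol();
  NumericMatrix out(k, n);
  for (int j = 0; j < k; ++j) {
    const double* w = &W(0, j);
    const double* p = &P(0, j);
    const double* a = &A(0, j);
    const double amp = ampAlpha[j];
    for (int i = 0; i < n; ++i)
      out(j, i) = noiseSd * w[i] + bgSd * p[i] + amp * a[i] * mod[i];
  }
  return out;
}
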