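// Sliding-window computation of the 14 time-domain features for one
// channel. Hot loop of the feature-extraction stage; the R functions
// compute_feature() / feature_block() are the reference implementation and
// the test suite checks this kernel against them.
//
// Conventions (must match R/features.R exactly): sgn(u) in the counting
// features is the indicator u > 0 (ties count 0); ZC counts sign changes
// of the demeaned window; sd uses the sample (N-1) denominator with a
// two-pass sum; logs are natural; |x| is floored at 1e-12 inside LD's log;
// MFL floors the summed squared differences at 1e-12; V3 is the signed
// cube root.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LD_EPS = 1e-12;

// x: samples (already left-padded by the caller as needed); windows of
// `win` samples end at first_end, first_end + step, ... Returns 14 x K.
// [[Rcpp::export]]
NumericMatrix window_features_cpp(NumericVector x, int win, int step,
                                  int first_end) {
  const int T = x.size();
  if (first_end < win || first_end > T)
    stop("first_end must lie in [win, length(x)]");
  const int K = (T - first_end) / step + 1;
  NumericMatrix out(14, K);
  const int half = win / 2;
  const double w_lo = 0.25 * win, w_hi = 0.75 * win;

  for (int j = 0; j < K; ++j) {
    const int e = first_end + j * step;   // 1-based end index
    const int s0 = e - win;               // 0-based start offset
    double sum = 0.0, sumsq = 0.0, sumabs = 0.0, sumcube = 0.0,
           sumlog = 0.0, sumabs_first = 0.0, sumwma = 0.0;
    for (int k = 0; k < win; ++k) {
      const double v = x[s0 + k];
      const double av = std::fabs(v);
      sum += v; sumsq += v * v; sumabs += av; sumcube += v * v * v;
      sumlog += std::log(av > LD_EPS ? av : LD_EPS);
      if (k < half) sumabs_first += av;
      const double w = (k + 1 >= w_lo && k + 1 <= w_hi) ? 1.0 : 0.5;
      sumwma += w * av;
    }
    const double mu = sum / win;
    double ss = 0.0;                      // two-pass variance, matches R sd()
    for (int k = 0; k < win; ++k) {
      const double d = x[s0 + k] - mu;
      ss += d * d;
    }
    const double sd = std::sqrt(ss / (win - 1));

    int zc = 0, ssc = 0, wa = 0, mpr = 0;
    double wl = 0.0, sumd2 = 0.0;
    double prev = x[s0], prev_d = 0.0;
    for (int k = 1; k < win; ++k) {
      const double v = x[s0 + k];
      const double d = v - prev;
      const double ad = std::fabs(d);
      wl += ad; sumd2 += d * d;
      if (ad > sd) ++wa;
      if (-(prev - mu) * (v - mu) > 0.0) ++zc;
      if (k >= 2 && -(d * prev_d) > 0.0) ++ssc;
      prev_d = d;
      prev = v;
    }
    for (int k = 0; k < win; ++k)
      if (std::fabs(x[s0 + k]) > sd) ++mpr;

    const double msq = sumsq / win;
    const double m3 = sumcube / win;
    out(0, j) = zc;                                   // ZC
    out(1, j) = ssc;                                  // SSC
    out(2, j) = wl;                                   // WL
    out(3, j) = wa;                                   // WA
    out(4, j) = sumabs / win;                         // MAB
    out(5, j) = msq;                                  // MSQ
    out(6, j) = std::sqrt(msq);                       // RMS
    out(7, j) = (m3 >= 0 ? std::cbrt(m3) : -std::cbrt(-m3));   // V3
    out(8, j) = std::exp(sumlog / win);               // LD
    out(9, j) = std::sqrt(sumd2 / (win - 1));         // DABS
    out(10, j) = 0.5 * std::log(sumd2 > LD_EPS ? sumd2 : LD_EPS);  // MFL
    out(11, j) = mpr;                                 // MPR
    out(12, j) = (sumabs_first - (sumabs - sumabs_first)) / half;  // MAVS
    out(13, j) = sumwma / win;                        // WMA
  }
  return out;
}
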