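// Shared WFPT density kernel.
//
// Standardised first-passage density at the lower boundary for a
// unit-variance Wiener process (drift 0, boundary 1, relative start w),
// evaluated by whichever of the small-time / large-time series needs fewer
// terms for a per-term truncation tolerance of 1e-7. The exponential and
// sine factors inside the large-time sum are advanced by recurrences
// (exp(-k^2 c) via q^(2k+1) ratios, sin(k pi w) via the Chebyshev
// three-term recurrence) so each evaluation needs O(1) transcendental calls.

#ifndef DLENS_WFPT_DENSITY_H
#define DLENS_WFPT_DENSITY_H

#include <cmath>
#include <Rinternals.h>

namespace dlens {

const double LOG_FLOOR = -700.0;
const double SERIES_EPS = 1e-7;

inline double wfpt_f0(double tt, double w) {
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * SERIES_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * SERIES_EPS * std::sqrt(2.0 * M_PI * tt)));
    if (ks < std::sqrt(tt) + 1.0) ks = std::sqrt(tt) + 1.0;
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * SERIES_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * SERIES_EPS) /
                   (M_PI * M_PI * tt));
    if (kl < 1.0 / (M_PI * std::sqrt(tt))) kl = 1.0 / (M_PI * std::sqrt(tt));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  double p = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2);
    int hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double z = w + 2.0 * k;
      p += z * std::exp(-z * z / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {        // large-time expansion with recurrences
    int K = (int)std::ceil(kl);
    double c = M_PI * M_PI * tt / 2.0;
    double q2 = std::exp(-2.0 * c);   // ratio increment q^2
    double e = std::exp(-c);          // exp(-k^2 c) at k = 1
    double r = e * q2;                // q^(2k+1) at k = 1
    double s1 = std::sin(M_PI * w);   // sin(k pi w) by Chebyshev recurrence
    double s0 = 0.0;
    double twoc = 2.0 * std::cos(M_PI * w);
    double s = s1;
    for (int k = 1; k <= K; ++k) {
      p += k * e * s;
      e *= r;
      r *= q2;
      double s2 = twoc * s - s0;
      s0 = s; s = s2;
    }
    (void)s1;
    p *= M_PI;
  }
  return p;
}

// log joint density of absorption at the given boundary at time rt;
// upper = 1 codes the upper (positive-outcome) boundary
inline double wfpt_logd(double rt, int upper, double v, double a,
                        double tau, double beta) {
  double t = rt - tau;
  if (!(t > 0.0) || !(a > 0.0) || !(beta > 0.0) || !(beta < 1.0) ||
      !R_FINITE(v) || !R_FINITE(rt)) {
    return LOG_FLOOR;
  }
  double w = upper ? (1.0 - beta) : beta;
  double vv = upper ? -v : v;
  double tt = t / (a * a);
  double f0 = wfpt_f0(tt, w);
  if (!(f0 > 0.0)) return LOG_FLOOR;
  double logf = std::log(f0) - 2.0 * std::log(a) - vv * a * w - vv * vv * t / 2.0;
  if (!R_FINITE(logf) || logf < LOG_FLOOR) return LOG_FLOOR;
  return logf;
}

}  // namespace dlens

#endif
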