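#include <cmath>
#include <algorithm>
#include "wfpt.h"

#ifndef M_PI
#define M_PI 3.14159265358979323846
#endif

// First-passage-time density at the LOWER boundary of a Wiener process with
// unit diffusion, drift v, boundary separation a and relative start w = z/a.
// Evaluated with the standard pair of series expansions in normalised time
// u = t/a^2; the small-time and large-time expansions are both exact limits,
// and the cheaper one (fewer terms for truncation error <= eps on the
// normalised density) is selected per call.
double wfpt_lower(double t, double v, double a, double w, double eps) {
  if (t <= 0.0 || a <= 0.0) return 0.0;
  const double u = t / (a * a);

  // terms needed by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double f1;
  if (ks < kl) {               // small-time expansion
    const int K = (int)std::ceil(ks);
    const int lo = -((K - 1) / 2);
    const int hi = (int)std::ceil((K - 1) / 2.0);
    double s = 0.0;
    for (int k = lo; k <= hi; ++k) {
      const double wk = w + 2.0 * k;
      s += wk * std::exp(-wk * wk / (2.0 * u));
    }
    f1 = s / std::sqrt(2.0 * M_PI * u * u * u);
  } else {                     // large-time expansion
    const int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k)
      s += k * std::exp(-0.5 * k * k * M_PI * M_PI * u) * std::sin(k * M_PI * w);
    f1 = M_PI * s;
  }
  if (f1 < 0.0) f1 = 0.0;      // truncation can undershoot in the far tail

  return f1 * std::exp(-v * a * w - 0.5 * v * v * t) / (a * a);
}
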