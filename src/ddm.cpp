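#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, double v, double a, double w,
                               bool upper, double eps) {
  const int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    // density at the upper boundary equals the lower-boundary density of the
    // mirrored process (-v, 1-w)
    out[i] = upper ? wfpt_lower(t[i], -v, a, 1.0 - w, eps)
                   : wfpt_lower(t[i],  v, a,       w, eps);
  }
  return out;
}

// Euler-Maruyama simulation of n independent diffusion trials from z = a/2
// with unit diffusion coefficient.  Within-step boundary crossings are
// recovered with the Brownian-bridge crossing probability, which removes the
// leading O(sqrt(dt)) discretisation bias of naive thresholding.
// boundary: 1 = upper, -1 = lower, 0 = no crossing before t_max - ter.
// rt includes the non-decision time ter.
// [[Rcpp::export]]
List simulate_ddm_cpp(int n, double v, double a, double ter,
                      double dt, double t_max) {
  IntegerVector boundary(n);
  NumericVector rt(n);
  const double sdt = std::sqrt(dt);
  const double t_dec_max = t_max - ter;

  for (int i = 0; i < n; ++i) {
    double x = a / 2.0, t = 0.0;
    int b = 0;
    double tc = NA_REAL;
    while (t < t_dec_max) {
      const double x1 = x + v * dt + sdt * norm_rand();
      if (x1 >= a) {
        b = 1;  tc = t + dt * (a - x) / (x1 - x);  break;
      }
      if (x1 <= 0.0) {
        b = -1; tc = t + dt * x / (x - x1);        break;
      }
      // bridge crossing probabilities for an excursion within the step
      const double pu = std::exp(-2.0 * (a - x) * (a - x1) / dt);
      const double pl = std::exp(-2.0 * x * x1 / dt);
      const double uu = unif_rand();
      if (uu < pu)           { b = 1;  tc = t + 0.5 * dt; break; }
      else if (uu < pu + pl) { b = -1; tc = t + 0.5 * dt; break; }
      x = x1;
      t += dt;
    }
    if (b != 0 && tc <= t_dec_max) {
      boundary[i] = b;
      rt[i] = tc + ter;
    } else {
      boundary[i] = 0;
      rt[i] = NA_REAL;
    }
    if ((i & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}
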