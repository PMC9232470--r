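#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoidal-linear transfer function of the reduced two-variable model:
// H(x) = (aH*x - bH) / (1 - exp(-dH*(aH*x - bH))), with the y/dH limit at
// the removable singularity.
static inline double transfer(double x, double aH, double bH, double dH) {
  const double y = aH * x - bH;
  const double e = dH * y;
  if (std::fabs(e) < 1e-9) return 1.0 / dH;
  return y / (1.0 - std::exp(-e));
}

// Simulate n race trials of the two-population reduced attractor model.
// Each population has a slow NMDA-like gating variable S driven by
// self-excitation, mutual inhibition, a deterministic input current and an
// Ornstein-Uhlenbeck noise current.  The first population whose firing rate
// crosses `threshold` wins; `ndt` is added to the crossing time.
// choice: 1 = left population, -1 = right, 0 = no crossing by t_max.
// [[Rcpp::export]]
List simulate_nm_cpp(int n, double I_L, double I_R,
                     double J_self, double J_cross,
                     double aH, double bH, double dH,
                     double gamma, double tau_S,
                     double sigma_noise, double tau_noise,
                     double threshold, double ndt,
                     double dt, double t_max) {
  IntegerVector choice(n);
  NumericVector rt(n);
  const int n_steps = (int)std::ceil(t_max / dt);
  const double noise_decay = dt / tau_noise;
  const double noise_scale = sigma_noise * std::sqrt(dt / tau_noise);

  for (int i = 0; i < n; ++i) {
    double SL = 0.1, SR = 0.1;       // symmetric initial gating
    double nL = 0.0, nR = 0.0;       // OU noise currents
    int ch = 0;
    double tc = NA_REAL;
    for (int s = 1; s <= n_steps; ++s) {
      const double xL = J_self * SL - J_cross * SR + I_L + nL;
      const double xR = J_self * SR - J_cross * SL + I_R + nR;
      const double rL = transfer(xL, aH, bH, dH);
      const double rR = transfer(xR, aH, bH, dH);
      if (rL >= threshold || rR >= threshold) {
        // simultaneous crossings within one step: larger rate wins,
        // exact ties broken by the trial's random stream
        if (rL > rR) ch = 1;
        else if (rR > rL) ch = -1;
        else ch = (unif_rand() < 0.5) ? 1 : -1;
        tc = s * dt;
        break;
      }
      SL += dt * (-SL / tau_S + (1.0 - SL) * gamma * rL);
      SR += dt * (-SR / tau_S + (1.0 - SR) * gamma * rR);
      if (SL < 0.0) SL = 0.0; else if (SL > 1.0) SL = 1.0;
      if (SR < 0.0) SR = 0.0; else if (SR > 1.0) SR = 1.0;
      nL += -nL * noise_decay + noise_scale * norm_rand();
      nR += -nR * noise_decay + noise_scale * norm_rand();
    }
    choice[i] = ch;
    rt[i] = (ch == 0) ? NA_REAL : tc + ndt;
    if ((i & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}
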