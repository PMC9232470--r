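#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "wfpt.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hierarchical drift-diffusion sampler.
//
// Model: per subject i and task condition c, the trial likelihood is a
// mixture of the Wiener first-passage density (accuracy coding: the correct
// response is absorption at the upper boundary, start point a/2, unit
// diffusion) with weight (1 - q), and a uniform outlier component with
// weight q spread over both responses and [0, t_max].  Subject-level
// parameters are drawn from condition-specific group normals for the
// parameters named in `varies`, and from a single group normal otherwise.
//
// Sampler: component-wise random-walk Metropolis with per-component step
// sizes adapted towards a 0.44 acceptance rate during burn-in only (the
// post-burn-in kernel is a fixed Metropolis kernel, preserving detailed
// balance).  All randomness comes from R's RNG, so chains are reproducible
// under set.seed().
// ---------------------------------------------------------------------------

static const double WFPT_EPS = 1e-7;
static const int N_COND = 4;

// accuracy-coded boundary density
static inline double bound_density(double t_dec, double v, double a, int correct) {
  if (correct) return wfpt_lower(t_dec, -v, a, 0.5, WFPT_EPS);
  return wfpt_lower(t_dec, v, a, 0.5, WFPT_EPS);
}

static inline double mix_loglik(double rt, int correct, double v, double a,
                                double ter, double q, double t_max) {
  const double td = rt - ter;
  const double f = (td > 0.0) ? bound_density(td, v, a, correct) : 0.0;
  const double dens = (1.0 - q) * f + q / (2.0 * t_max);
  return (dens > 0.0) ? std::log(dens) : R_NegInf;
}

struct ParamLayout {
  int nlev[3];     // 4 if condition-specific, else 1
  int offset[3];   // cumulative offsets into the per-subject compact layout
  int sdim;        // total per-subject parameters
  ParamLayout(const LogicalVector& varies) {
    sdim = 0;
    for (int p = 0; p < 3; ++p) {
      nlev[p] = varies[p] ? N_COND : 1;
      offset[p] = sdim;
      sdim += nlev[p];
    }
  }
  inline int lev(int p, int cond) const { return nlev[p] == 1 ? 0 : cond; }
};

// [[Rcpp::export]]
List hddm_chain_cpp(NumericVector rt, IntegerVector correct,
                    IntegerVector subj, IntegerVector cond,
                    int n_subj, LogicalVector varies,
                    int n_iter, int n_burn,
                    double q, double t_max,
                    List init, int subj_keep) {
  const int n_trials = rt.size();
  ParamLayout L(varies);

  // priors and hard bounds (v, a, ter)
  const double muM[3]  = {2.0, 1.5, 0.30};
  const double muS[3]  = {3.0, 1.0, 0.25};
  const double muLo[3] = {-12.0, 0.10, 0.05};
  const double muHi[3] = { 12.0, 10.0, 1.00};
  const double xLo[3]  = {-12.0, 0.05, 0.005};
  const double xHi[3]  = { 12.0, 10.0, 2.50};
  const double sigLo = 1e-3, sigHi = 5.0;

  // parameter state (mu/sig use p*4+l slots; x uses compact layout)
  std::vector<double> mu(12), sig(12);
  std::vector<double> x((size_t)n_subj * L.sdim);
  {
    NumericVector mu0 = init["mu"], sig0 = init["sig"], x0 = init["x"];
    for (int k = 0; k < 12; ++k) { mu[k] = mu0[k]; sig[k] = sig0[k]; }
    for (size_t k = 0; k < x.size(); ++k) x[k] = x0[k];
  }
  // enforce bounds on initial values
  for (int p = 0; p < 3; ++p)
    for (int l = 0; l < L.nlev[p]; ++l) {
      int k = p * 4 + l;
      if (mu[k] < muLo[p]) mu[k] = muLo[p];
      if (mu[k] > muHi[p]) mu[k] = muHi[p];
      if (sig[k] < 0.05) sig[k] = 0.05;
      if (sig[k] > sigHi) sig[k] = sigHi;
      for (int i = 0; i < n_subj; ++i) {
        double& xi = x[(size_t)i * L.sdim + L.offset[p] + l];
        if (xi < xLo[p]) xi = xLo[p] + 1e-3;
        if (xi > xHi[p]) xi = xHi[p] - 1e-3;
      }
    }

  auto xval = [&](int i, int p, int c) -> double {
    return x[(size_t)i * L.sdim + L.offset[p] + L.lev(p, c)];
  };

  // trial index blocks
  std::vector<std::vector<int> > trials_ic((size_t)n_subj * N_COND);
  std::vector<std::vector<int> > trials_i(n_subj);
  for (int t = 0; t < n_trials; ++t) {
    trials_ic[(size_t)subj[t] * N_COND + cond[t]].push_back(t);
    trials_i[subj[t]].push_back(t);
  }

  // likelihood cache
  std::vector<double> cur_ll(n_trials);
  bool ok = true;
  for (int t = 0; t < n_trials; ++t) {
    cur_ll[t] = mix_loglik(rt[t], correct[t],
                           xval(subj[t], 0, cond[t]),
                           xval(subj[t], 1, cond[t]),
                           xval(subj[t], 2, cond[t]), q, t_max);
    if (!R_finite(cur_ll[t])) { ok = false; break; }
  }
  if (!ok) return List::create(_["ok"] = false);

  // proposal scales
  std::vector<double> s_mu(12, 0.08), s_sig(12, 0.20);
  std::vector<double> s_x((size_t)n_subj * L.sdim);
  for (int i = 0; i < n_subj; ++i)
    for (int p = 0; p < 3; ++p) {
      double s0 = (p == 0) ? 0.25 : (p == 1 ? 0.10 : 0.02);
      for (int l = 0; l < L.nlev[p]; ++l)
        s_x[(size_t)i * L.sdim + L.offset[p] + l] = s0;
    }
  auto adapt = [](double& s, bool acc, double gain) {
    s *= std::exp(gain * ((acc ? 1.0 : 0.0) - 0.44));
    if (s < 1e-4) s = 1e-4;
    if (s > 5.0)  s = 5.0;
  };

  // output storage
  const int n_keep = n_iter - n_burn;
  const int n_group = 2 * L.sdim;
  NumericMatrix group_draws(n_keep, n_group);
  NumericVector deviance(n_keep);
  const int thin = std::max(1, n_keep / std::max(1, subj_keep));
  const int n_subj_rows = (n_keep + thin - 1) / thin;
  NumericMatrix subj_draws(n_subj_rows, (int)x.size());
  std::vector<double> x_sum(x.size(), 0.0);

  std::vector<double> new_ll;
  new_ll.reserve(512);

  for (int it = 0; it < n_iter; ++it) {
    const bool burn = it < n_burn;
    const double gain = burn ? std::min(0.25, 5.0 / (it + 10.0)) : 0.0;

    // --- group-level updates -------------------------------------------
    for (int p = 0; p < 3; ++p) {
      for (int l = 0; l < L.nlev[p]; ++l) {
        const int k = p * 4 + l;
        // group mean
        {
          const double prop = mu[k] + s_mu[k] * norm_rand();
          bool acc = false;
          if (prop > muLo[p] && prop < muHi[p]) {
            double d = (std::pow(mu[k] - muM[p], 2) - std::pow(prop - muM[p], 2)) /
                       (2.0 * muS[p] * muS[p]);
            const double inv2s2 = 1.0 / (2.0 * sig[k] * sig[k]);
            for (int i = 0; i < n_subj; ++i) {
              const double xi = x[(size_t)i * L.sdim + L.offset[p] + l];
              d += (std::pow(xi - mu[k], 2) - std::pow(xi - prop, 2)) * inv2s2;
            }
            if (d >= 0.0 || unif_rand() < std::exp(d)) { mu[k] = prop; acc = true; }
          }
          if (burn) adapt(s_mu[k], acc, gain);
        }
        // group sd (random walk on log scale, half-normal(0,1) prior)
        {
          const double lprop = std::log(sig[k]) + s_sig[k] * norm_rand();
          const double prop = std::exp(lprop);
          bool acc = false;
          if (prop > sigLo && prop < sigHi) {
            double d = 0.5 * (sig[k] * sig[k] - prop * prop);        // prior
            d += lprop - std::log(sig[k]);                           // Jacobian
            const double dinv = 1.0 / (2.0 * prop * prop) - 1.0 / (2.0 * sig[k] * sig[k]);
            double ss = 0.0;
            for (int i = 0; i < n_subj; ++i) {
              const double e = x[(size_t)i * L.sdim + L.offset[p] + l] - mu[k];
              ss += e * e;
            }
            d += n_subj * (std::log(sig[k]) - lprop) - ss * dinv;
            if (d >= 0.0 || unif_rand() < std::exp(d)) { sig[k] = prop; acc = true; }
          }
          if (burn) adapt(s_sig[k], acc, gain);
        }
      }
    }

    // --- subject-level updates -----------------------------------------
    for (int i = 0; i < n_subj; ++i) {
      for (int p = 0; p < 3; ++p) {
        for (int l = 0; l < L.nlev[p]; ++l) {
          const size_t xi_idx = (size_t)i * L.sdim + L.offset[p] + l;
          const int k = p * 4 + l;
          const double old = x[xi_idx];
          const double prop = old + s_x[xi_idx] * norm_rand();
          bool acc = false;
          if (prop > xLo[p] && prop < xHi[p]) {
            double d = (std::pow(old - mu[k], 2) - std::pow(prop - mu[k], 2)) /
                       (2.0 * sig[k] * sig[k]);
            const std::vector<int>& block =
              (L.nlev[p] == 1) ? trials_i[i] : trials_ic[(size_t)i * N_COND + l];
            new_ll.resize(block.size());
            double dll = 0.0;
            for (size_t b = 0; b < block.size(); ++b) {
              const int t = block[b];
              const double vv  = (p == 0) ? prop : xval(i, 0, cond[t]);
              const double aa  = (p == 1) ? prop : xval(i, 1, cond[t]);
              const double tt  = (p == 2) ? prop : xval(i, 2, cond[t]);
              new_ll[b] = mix_loglik(rt[t], correct[t], vv, aa, tt, q, t_max);
              dll += new_ll[b] - cur_ll[t];
            }
            d += dll;
            if (R_finite(d) && (d >= 0.0 || unif_rand() < std::exp(d))) {
              x[xi_idx] = prop;
              for (size_t b = 0; b < block.size(); ++b) cur_ll[block[b]] = new_ll[b];
              acc = true;
            }
          }
          if (burn) adapt(s_x[xi_idx], acc, gain);
        }
      }
    }

    // --- storage --------------------------------------------------------
    if (!burn) {
      const int row = it - n_burn;
      int col = 0;
      for (int p = 0; p < 3; ++p)
        for (int l = 0; l < L.nlev[p]; ++l)
          group_draws(row, col++) = mu[p * 4 + l];
      for (int p = 0; p < 3; ++p)
        for (int l = 0; l < L.nlev[p]; ++l)
          group_draws(row, col++) = sig[p * 4 + l];
      double sll = 0.0;
      for (int t = 0; t < n_trials; ++t) sll += cur_ll[t];
      deviance[row] = -2.0 * sll;
      for (size_t kk = 0; kk < x.size(); ++kk) x_sum[kk] += x[kk];
      if (row % thin == 0) {
        const int srow = row / thin;
        for (size_t kk = 0; kk < x.size(); ++kk) subj_draws(srow, (int)kk) = x[kk];
      }
    }
    if ((it & 0x1F) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector x_mean((int)x.size());
  for (size_t kk = 0; kk < x.size(); ++kk) x_mean[(int)kk] = x_sum[kk] / n_keep;

  return List::create(_["ok"] = true,
                      _["group"] = group_draws,
                      _["deviance"] = deviance,
                      _["subj"] = subj_draws,
                      _["x_mean"] = x_mean,
                      _["subj_thin"] = thin);
}

// Total deviance (-2 log-likelihood) of the data at a fixed set of
// subject-level parameters in the compact layout used by hddm_chain_cpp.
// [[Rcpp::export]]
double hddm_deviance_cpp(NumericVector rt, IntegerVector correct,
                         IntegerVector subj, IntegerVector cond,
                         int n_subj, LogicalVector varies,
                         NumericVector x, double q, double t_max) {
  ParamLayout L(varies);
  double sll = 0.0;
  const int n_trials = rt.size();
  for (int t = 0; t < n_trials; ++t) {
    const int i = subj[t];
    const double v   = x[i * L.sdim + L.offset[0] + L.lev(0, cond[t])];
    const double a   = x[i * L.sdim + L.offset[1] + L.lev(1, cond[t])];
    const double ter = x[i * L.sdim + L.offset[2] + L.lev(2, cond[t])];
    sll += mix_loglik(rt[t], correct[t], v, a, ter, q, t_max);
  }
  return -2.0 * sll;
}

// Vectorised mixture log-likelihood for single trials (used by the R-level
// ddm_trial_loglik and by tests).
// [[Rcpp::export]]
NumericVector trial_loglik_cpp(NumericVector rt, IntegerVector correct,
                               double v, double a, double ter,
                               double q, double t_max) {
  const int n = rt.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t)
    out[t] = mix_loglik(rt[t], correct[t], v, a, ter, q, t_max);
  return out;
}
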