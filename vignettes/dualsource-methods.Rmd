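---
title: "Models and methods behind dualsource"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualsource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dualsource` implements the full modelling stack for a two-alternative
motion-discrimination experiment in which the coherent motion signal is
split across two apertures: staircase calibration of per-observer coherence
levels, synthetic trial generation, hierarchical Bayesian drift-diffusion
fitting with model comparison, and a biologically motivated attractor-network
account of the same behavioural pattern.  This vignette is the package's own
record of the models, conventions and design choices; the numbers a given
installation produces come from the test suite and `scripts/acceptance.R`,
not from this document.

## The experimental design being emulated

Observers judge the net direction (left/right) of random-dot motion shown in
two tilted apertures.  Four task conditions form a 2 x 2 design: combined
coherence high (`c_high`) or low (`c_low`), carried by a single source or
split over two sources.  With two sources the directions are congruent in
the high-coherence condition (`c_low` and `c_high - c_low`, same sign) and
incongruent in the low-coherence condition (`c_high` against
`-(c_high - c_low)`), so the *net* coherence always equals its single-source
baseline.  A session is 432 trials in 6 blocks of 72 (16 per task condition
plus 8 easy 60%-coherence control trials per block, directions balanced
within every block).  Two groups differ only in aperture angle (20 vs 45
degrees).  `generate_design()` reproduces this structure exactly;
condition counts, direction balance and net-coherence conservation are
invariants tested to machine precision.

## Staircase calibration

Two fixed-step staircases on log10 coherence run interleaved, both starting
at 31.6% coherence, moving up 0.1 log units after an error and down 0.074
after `n` consecutive correct responses (`n` = 2 or 3).  Each stops at 10
reversals; the threshold is the arithmetic mean of the coherences at the
last 9 reversals, following the experimental protocol.  With the 0.74
down/up step ratio these rules converge near 74% (2-down/1-up) and 83%
(3-down/1-up) correct.

Two conventions were genuinely open and are fixed as follows:

* **Interleaving** is strict alternation (a finished staircase is skipped);
  random mixing is available via `schedule = "random"`.  The protocol says
  only "interleaved"; alternation maximises reproducibility.
* **Reversal definition**: a level change whose direction differs from the
  previous change; the initial monotone run is not a reversal, and the
  recorded reversal level is the turning level (the level from which the
  new move departs).

`asymptotic_accuracy()` estimates the converged percent correct by running
far past the experimental stopping rule (>= 200 reversals) and averaging
late reversal levels *in the step domain* (a geometric mean of coherences).
The equilibrium of a fixed-step random walk is defined on its step scale;
averaging the alternating reversal levels linearly instead inflates the
estimate by 2-3 percentage points.  With a smooth logistic observer this
reproduces the 74%/83% convergence targets, and the converged level is
rule-determined: halving or doubling the observer's slope moves the
converged *coherence*, not the converged percent correct.  The validation
observer is logistic in log10 coherence with zero lapse (default 75% point
at 12% coherence, slope 8 per log10 unit); a lapse-free smooth observer is
required by the convergence theory, and lapse-rate estimation is out of
scope.

## Drift-diffusion core

The basic DDM has three parameters: drift rate `v`, boundary separation
`a` and non-decision time `Ter`; the start point is fixed at `a/2`
(unbiased) and there are no across-trial variability parameters.  The
diffusion coefficient is fixed at `sigma = 1` - the convention of the
hierarchical toolboxes this model family is usually fitted with - so
posterior scales are comparable with those fits; Ratcliff's `s = 0.1`
convention would simply rescale all parameters.

Closed forms for the unbiased case serve as oracles throughout the tests:
the probability of absorbing at the correct boundary is
`1 / (1 + exp(-v a))` and the mean decision time is
`(a / 2v) tanh(v a / 2)`.

Numerical choices:

* **Trial simulation** (`simulate_ddm()`) uses Euler-Maruyama with a 1 ms
  default step and a Brownian-bridge within-step crossing correction
  (crossing probability `exp(-2 (a - x0)(a - x1) / dt)` per step and
  boundary).  The correction removes the leading `O(sqrt(dt))` bias of
  naive thresholding; at 1 ms the residual bias is below the Monte-Carlo
  error of the trial counts used anywhere in the package.
* **Likelihood** (`wfpt_density()`) evaluates the Wiener first-passage
  density by the standard small-time/large-time series pair, switching by
  the usual truncation-error bound at tolerance `1e-7`.  Both expansions
  are exact limits; the switch point is purely numerical.
* **Outlier mixture**: the trial likelihood is
  `(1 - q) f_wiener + q / (2 t_max)` with `q = 0.05`, i.e. 5% of responses
  are attributed to a uniform distribution over both responses and the
  4-second response window.  The protocol states the uniform but not its
  support; the response window is the natural choice and makes responses
  faster than `Ter` finitely likely rather than impossible.

## Hierarchical estimation

Four variants are compared: `v+a`, `v+ter`, `a+ter` and `v+a+ter` name the
parameters allowed to differ between the four task conditions; every
parameter differs between subjects in every variant, with subject values
drawn from condition-specific group normals.  Group priors are weakly
informative and span typical 2AFC fits: means `v ~ N(2, 3)`,
`a ~ N(1.5, 1)` truncated above 0.1, `Ter ~ N(0.3, 0.25)` truncated to
[0.05, 1]; group SDs are half-normal(0, 1).  Subject-level draws are
bounded away from impossible values by proposal rejection; the group normal
density is used without renormalising for that truncation, which is
negligible at these scales.

The sampler is component-wise random-walk Metropolis.  Step sizes adapt
towards 44% acceptance during burn-in only, so the post-burn-in kernel is a
fixed Metropolis kernel and detailed balance holds for the retained draws.
Initial values are data-informed (EZ-style: `v` from cell accuracy at a
nominal boundary, `Ter` from the fastest responses) with multiplicative
jitter per chain; if the likelihood is non-finite at initialisation the
init is redrawn up to a retry cap and then fails loudly.  All randomness
flows through R's RNG, so fits are byte-reproducible given `seed`.

The protocol budget is 20,000 samples per chain with 4,000 discarded, five
chains; that budget is the default of `hddm()`.  The package's own tests
use 3 chains x 4,000 samples (1,000 burn-in) for the experiment-scale
recovery study and 3 x 2,500 for variant comparisons - sizes chosen so the
whole study runs comfortably at a desk while leaving the convergence
diagnostic comfortably under the 1.1 criterion.  Convergence is assessed
with the Gelman-Rubin potential scale reduction factor per group-level
parameter; model comparison uses `DIC = Dbar + pD` with
`pD = Dbar - D(posterior mean)` evaluated at the posterior mean of the
subject-level parameters.  DIC at this focus is known to penalise
hierarchical freedom only partially, so on data generated with a single
varying parameter the full variant can still win; what the package asserts,
and what model selection is used for scientifically, is that the winning
variant contains the parameters that truly vary.

Directional hypotheses about group means are tested with
`posterior_prob_greater()`, the proportion of paired draws (same chain and
iteration) with A > B.  Whether the original analyses paired draws or
measured density non-overlap is not stated anywhere authoritative; paired
draws are the standard operationalisation and respect posterior
correlation.  The self-comparison returns 0.5 by convention, since a strict
inequality on identical draws would read as certainty.

## The synthetic cohort generator

`generate_cohort()` is the generative twin of the fitted model: subject
parameters are drawn from the condition-specific group normals (truncated
to positive `a` and `Ter`), each subject's full 432-trial design is
simulated through the accuracy-coded DDM, and 5% of responses are replaced
by uniform outliers to match the fitted mixture.  Control trials get a
drift from the same linear coherence-to-drift map used nowhere else
(`v = 5.3 * net coherence`, a slope chosen once so the high-coherence level
sits near 83% accuracy at the default boundary, mirroring what the
staircase calibration achieves); control trials exist only to exercise the
exclusion filter and are dropped from analysis.  No empirical map from
coherence to drift is claimed - the linear map is a repository convention.

Default group means emulate the qualitative empirical pattern: congruent
double-source drift below its baseline drift, incongruent double-source
boundary below its baseline boundary, non-decision time constant
(`v` = 0.85, 1.06, 0.80, 0.80; `a` = 1.5, 1.5, 1.3, 1.5; `Ter` = 0.35 for
CON, CON_BSL, INC, INC_BSL; SDs 0.3, 0.15, 0.05).  What passing recovery
tests show is that the estimation machinery works on data that obey its
assumptions at realistic sizes; they cannot show that real data obey those
assumptions - real RT distributions carry contaminants, slow drifts and
sequential effects that this generator deliberately omits.

## Preprocessing and statistics

`preprocess()` applies the study's rules: responses faster than 250 ms and
non-responses are removed; a subject whose accuracy over any consecutive
block pair (1-2, 3-4, 5-6, over all responded trials including control)
falls below 60% is excluded entirely (applied retrospectively, since online
early termination is not reproducible offline); control trials are then
dropped.  The filter is idempotent.  Condition summaries pool correct and
error RTs by default (the reporting convention is not stated; a
correct-only switch exists).  `mixed_anova()` is the classical
sums-of-squares repeated-measures decomposition via `stats::aov` with
`Error(subject/(coherence*source))` strata and aperture group as the
between factor, reporting F, dfs, p and partial eta squared;
`power_paired_t()` is the exact noncentral-t power of the two-sided paired
t-test.  Bayes factors and Levene's test are deliberately not implemented:
they are off-the-shelf statistics outside this package's core.

## The extended attractor model

The neural-mass model is the standard two-variable mean-field reduction of
a spiking attractor network: two populations with slow gating variables
`S`, self-excitation `J_self`, mutual inhibition `J_cross`, the
sigmoidal-linear transfer `H(x) = (a_H x - b_H)/(1 - exp(-d_H (a_H x - b_H)))`,
and Ornstein-Uhlenbeck noise currents.  The package extends its input
currents for two sources:

```
I_in,L = J_ext [ alpha mu (1 + c1) + (1 - alpha) mu (1 + c2) ] + beta I_0
I_in,R = J_ext [ alpha mu (1 - c1) + (1 - alpha) mu (1 - c2) ] + beta I_0
```

with `J_ext = 5.2e-4` nA/Hz, `I_0 = 0.321` nA, `mu = 35` Hz.  `alpha`
splits the input weight between the dominant (`c1`) and secondary (`c2`)
source; the two weights always sum to `mu`, and the same formula is applied
verbatim to single-source conditions (where `c2 = 0`, so the secondary
aperture contributes symmetric drive and no evidence).  `beta` multiplies
the non-selective background current in the incongruent double-source
condition only and is 1 elsewhere; because the recurrent input uses `I_in`
as the full external drive, `I_0` is never counted twice.

Under this reading the empirically observed pattern pins down the regime
algebraically: the congruent double-source condition carries effective
evidence `alpha c_low + (1 - alpha)(c_high - c_low)`, which falls below its
baseline's `alpha c_high` exactly when `alpha > 0.5`; and the incongruent
condition carries *more* effective evidence than its baseline whenever
`alpha > 0.5`, so its lower accuracy and faster responses require
`beta > 1` (a raised background lifts both populations towards threshold -
less evidence needs accumulating, the model's speed-accuracy trade-off).
The simulated qualifying region therefore sits inside
`{alpha > 0.5} x {beta > 1}`, which the acceptance tests check on a coarse
grid with a Monte-Carlo guard band: a cell qualifies only if all four
directional inequalities exceed `guard_z` combined standard errors, and is
flagged indeterminate otherwise.

Constants not fixed by the study's description (the reduction's supplement
is not part of this package's sources) use the published two-variable
defaults: `a_H = 270`, `b_H = 108`, `d_H = 0.154`, `gamma = 0.641`,
`tau_S = 100` ms, `J_self = 0.2609` nA, `J_cross = 0.0497` nA,
`sigma_noise = 0.02` nA, `tau_noise = 2` ms, decision threshold 15 Hz on
the instantaneous rate, Euler step 0.5 ms, symmetric initial gating
`S = 0.1`, and a fixed 0.3 s non-decision offset (any constant offset
cancels in the performance differences the model is used for).  All are
arguments of `nm_params()`.  Simultaneous threshold crossings within one
step go to the larger rate, exact ties to the trial's random stream.  This
model is simulated, never fitted: it demonstrates sufficiency of the
mechanism, and its absolute accuracies at these constants run higher than
human performance - only the directions of the condition differences are
scientifically meaningful here.

## Known limitations

* DIC with subject-level focus under-penalises hierarchical complexity (see
  above); users comparing variants should read the winning variant's
  composition, not over-interpret small DIC gaps.
* The generator and fitter share the same likelihood family, so recovery
  tests validate machinery, not model adequacy for real data.
* The staircase asymptote and the attractor-model region checks are
  stochastic properties verified at fixed seeds and stated replicate
  counts; they hold in distribution, not trial-by-trial.
* Posterior scales are comparable to, but not identical with, fits from
  other toolboxes whose exact priors differ.
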