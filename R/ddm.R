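# Drift-diffusion primitives: trial simulation, closed-form oracles for the
# unbiased (z = a/2) constant-drift case, the Wiener first-passage-time
# density, and the outlier-mixture trial likelihood.
#
# Conventions: unit diffusion coefficient (sigma = 1), start point fixed at
# a/2, accuracy coding (the upper boundary is the correct response).  No
# across-trial variability parameters.

#' Core drift-diffusion parameters
#'
#' Bundles the three core parameters of the basic drift-diffusion model:
#' drift rate `v` (evidence units per second), boundary separation `a`
#' (evidence units) and non-decision time `ter` (seconds).  The start point
#' is fixed at `a/2` (unbiased) and the diffusion coefficient at 1.
#'
#' @param v Drift rate. Positive values drive the process towards the upper
#'   (correct) boundary.
#' @param a Boundary separation; must be positive.
#' @param ter Non-decision time in seconds; must be non-negative.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v = 1, a = 2, ter = 0.3)
#' @export
ddm_params <- function(v, a, ter = 0) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a positive finite scalar")
  if (!is.numeric(ter) || length(ter) != 1L || !is.finite(ter) || ter < 0)
    stop("'ter' must be a non-negative finite scalar")
  structure(list(v = v, a = a, ter = ter), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.4g, a = %.4g, Ter = %.4g s (z = a/2, sigma = 1)\n",
              x$v, x$a, x$ter))
  invisible(x)
}

#' Probability of a correct (upper-boundary) response
#'
#' Closed-form absorption probability at the upper boundary for an unbiased
#' diffusion (start `a/2`, unit diffusion): `1 / (1 + exp(-v * a))`.  Depends
#' on the product `v * a` only; equals 0.5 at `v = 0` by continuity.
#'
#' @param v Drift rate (vectorised).
#' @param a Boundary separation, positive (vectorised).
#' @return Probability of absorption at the upper boundary.
#' @examples
#' ddm_choice_probability(1, 2)   # 0.8808
#' @export
ddm_choice_probability <- function(v, a) {
  if (any(a <= 0)) stop("'a' must be positive")
  1 / (1 + exp(-v * a))
}

#' Mean decision time of the unbiased diffusion
#'
#' Closed-form expected first-passage time (either boundary, excluding
#' non-decision time) for start `a/2` and unit diffusion:
#' `(a / (2 v)) * tanh(v * a / 2)`, with the limit `a^2 / 4` at `v = 0`.
#'
#' @inheritParams ddm_choice_probability
#' @return Mean decision time in seconds.
#' @export
ddm_mean_decision_time <- function(v, a) {
  if (any(a <= 0)) stop("'a' must be positive")
  out <- ifelse(abs(v) < 1e-8, a^2 / 4, (a / (2 * v)) * tanh(v * a / 2))
  as.numeric(out)
}

#' Simulate drift-diffusion trials
#'
#' Euler-Maruyama simulation of independent diffusion trials from the
#' midpoint `a/2`.  Within-step boundary excursions are recovered with the
#' Brownian-bridge crossing probability, so the discretisation bias is of
#' higher order than the naive thresholding scheme.  Trials that do not
#' absorb within `t_max - ter` of decision time are returned as
#' `boundary = "none"` with `rt = NA`.
#'
#' @param n Number of trials.
#' @param v,a,ter Drift rate, boundary separation (> 0), non-decision time
#'   (>= 0).  Alternatively pass a [ddm_params()] object as `v`.
#' @param dt Euler step in seconds (must be positive and at most 0.005).
#' @param t_max Response deadline in seconds; `rt` includes `ter`.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `boundary` (`"upper"`, `"lower"`,
#'   `"none"`) and `rt` (seconds, `NA` for none).
#' @examples
#' sim <- simulate_ddm(1000, v = 1, a = 2, ter = 0.3, seed = 1)
#' mean(sim$boundary == "upper")      # close to ddm_choice_probability(1, 2)
#' @export
simulate_ddm <- function(n, v, a, ter = 0, dt = 0.001, t_max = 4, seed = NULL) {
  if (inherits(v, "ddm_params")) { p <- v; v <- p$v; a <- p$a; ter <- p$ter }
  if (dt <= 0) stop("'dt' must be positive")
  if (dt > 0.005) stop("'dt' must be at most 0.005 s")
  if (a <= 0) stop("'a' must be positive")
  if (ter < 0) stop("'ter' must be non-negative")
  if (t_max <= ter) stop("'t_max' must exceed 'ter'")
  if (!is.null(seed)) set.seed(seed)
  res <- simulate_ddm_cpp(as.integer(n), v, a, ter, dt, t_max)
  data.frame(
    boundary = c("lower", "none", "upper")[res$boundary + 2L],
    rt = res$rt,
    stringsAsFactors = FALSE
  )
}

#' Wiener first-passage-time density
#'
#' Density of the first passage through one boundary of the unbiased
#' diffusion, evaluated by adaptive truncation of the small-time and
#' large-time series expansions (absolute error at most `eps` on the
#' normalised density).  `t` is measured from stimulus onset; mass before
#' `ter` is zero.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param v,a,ter As in [simulate_ddm()].
#' @param boundary `"upper"` (correct) or `"lower"` (error).
#' @param eps Series truncation tolerance.
#' @return Density values; 0 for `t <= ter`.
#' @export
wfpt_density <- function(t, v, a, ter = 0, boundary = c("upper", "lower"),
                         eps = 1e-7) {
  boundary <- match.arg(boundary)
  if (a <= 0) stop("'a' must be positive")
  wfpt_density_cpp(pmax(t - ter, 0), v, a, 0.5, boundary == "upper", eps)
}

#' Trial log-likelihood with uniform outlier mixture
#'
#' Log-likelihood of one or more observed (choice, RT) pairs under the
#' mixture in which a fraction `1 - outlier_frac` of trials follows the
#' Wiener first-passage density and `outlier_frac` follows a uniform
#' distribution over both responses and the response window `[0, t_max]`
#' (density `outlier_frac / (2 * t_max)`).  Responses faster than `ter`
#' receive only the outlier term, hence `-Inf` when `outlier_frac = 0`.
#'
#' @param rt Response time(s) in seconds.
#' @param correct Logical (or 0/1): response at the correct (upper) boundary?
#' @param v,a,ter Core DDM parameters.
#' @param outlier_frac Outlier mixture weight in `[0, 1)`.
#' @param t_max Response window in seconds; `rt` must not exceed it.
#' @return Log-likelihood per trial.
#' @examples
#' ddm_trial_loglik(0.2, TRUE, v = 1, a = 2, ter = 0.3,
#'                  outlier_frac = 0.05, t_max = 4)  # log(0.05 / 8)
#' @export
ddm_trial_loglik <- function(rt, correct, v, a, ter, outlier_frac = 0.05,
                             t_max = 4) {
  if (outlier_frac < 0 || outlier_frac >= 1)
    stop("'outlier_frac' must be in [0, 1)")
  if (a <= 0) stop("'a' must be positive")
  if (any(rt > t_max)) stop("'rt' must not exceed 't_max'")
  trial_loglik_cpp(rt, as.integer(as.logical(correct)), v, a, ter,
                   outlier_frac, t_max)
}
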