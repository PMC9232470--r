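# Extended two-population reduced attractor ("neural-mass") model of 2AFC
# motion decisions.  Two accumulators with self-excitation and mutual
# inhibition receive deterministic input currents
#
#   I_in,L = J_ext * [ alpha*mu*(1 + c1) + (1 - alpha)*mu*(1 + c2) ] + beta*I_0
#   I_in,R = J_ext * [ alpha*mu*(1 - c1) + (1 - alpha)*mu*(1 - c2) ] + beta*I_0
#
# where c1 is the dominant source's signed coherence, alpha in [0, 1] splits
# the input weight between the two sources (alpha = 0.5 is equal weighting;
# the two weights always sum to mu), and beta scales the non-selective
# background current in the incongruent double-source condition only
# (beta = 1 elsewhere).  beta > 1 raises both baselines, effectively lowering
# the decision threshold: the model's speed-accuracy trade-off mechanism.

#' Neural-mass model parameters
#'
#' Constants of the reduced two-variable attractor model plus the two
#' source-integration extensions.  Input-current constants follow the study
#' conventions (`J_ext = 5.2e-4` nA/Hz, `I_0 = 0.321` nA, `mu = 35` Hz); the
#' reduced-model constants are the published defaults of the two-variable
#' mean-field reduction (transfer gain 270 Hz/nA, threshold 108 Hz,
#' curvature 0.154 s, kinetic factor 0.641, NMDA time constant 100 ms,
#' self-coupling 0.2609 nA, cross-coupling 0.0497 nA, OU noise 0.02 nA with
#' a 2 ms time constant).  All constants are configurable.
#'
#' @param alpha Source weight on the dominant input, in `[0, 1]`.
#' @param beta Background-input scaling (applied to incongruent double-source
#'   trials only).
#' @param J_ext Synaptic coupling (nA/Hz).
#' @param I_0 Background current baseline (nA).
#' @param mu Input-strength baseline (Hz).
#' @param a_H,b_H,d_H Transfer-function gain (Hz/nA), threshold (Hz) and
#'   curvature (s).
#' @param gamma Kinetic scaling of the gating variable.
#' @param tau_S Gating time constant (s).
#' @param J_self,J_cross Self- and cross-coupling (nA).
#' @param sigma_noise,tau_noise OU noise amplitude (nA) and time constant (s).
#' @param threshold Decision threshold on the population rate (Hz).
#' @param ndt Fixed non-decision offset added to the crossing time (s).
#' @param dt Euler step (s), at most 1 ms.
#' @param t_max Trial deadline (s).
#' @return An object of class `nm_params`.
#' @export
nm_params <- function(alpha = 0.5, beta = 1,
                      J_ext = 5.2e-4, I_0 = 0.321, mu = 35,
                      a_H = 270, b_H = 108, d_H = 0.154,
                      gamma = 0.641, tau_S = 0.100,
                      J_self = 0.2609, J_cross = 0.0497,
                      sigma_noise = 0.02, tau_noise = 0.002,
                      threshold = 15, ndt = 0.3,
                      dt = 5e-4, t_max = 4) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  if (any(c(J_ext, I_0, mu, tau_S, tau_noise, dt) <= 0))
    stop("J_ext, I_0, mu, tau_S, tau_noise and dt must be positive")
  if (dt > 1e-3) stop("'dt' must be at most 1 ms")
  structure(as.list(environment()), class = "nm_params")
}

#' @export
print.nm_params <- function(x, ...) {
  cat(sprintf(
    "Neural-mass parameters: alpha = %.3g, beta = %.4g, J_ext = %.3g nA/Hz, I_0 = %.3g nA, mu = %.3g Hz\n",
    x$alpha, x$beta, x$J_ext, x$I_0, x$mu))
  cat(sprintf("  threshold %.3g Hz, ndt %.3g s, dt %.3g ms, t_max %.3g s\n",
              x$threshold, x$ndt, 1000 * x$dt, x$t_max))
  invisible(x)
}

#' A stimulus condition for the neural-mass model
#'
#' @param c1 Signed coherence of the dominant source (`|c1| >= |c2|`).
#' @param c2 Signed coherence of the second source.
#' @param label Condition label; `beta` is applied only for `"INC"` (the
#'   incongruent double-source condition).
#' @return An object of class `nm_condition`.
#' @export
nm_condition <- function(c1, c2, label = c("CON", "CON_BSL", "INC", "INC_BSL")) {
  label <- match.arg(label)
  if (abs(c1) < abs(c2)) stop("'c1' must be the dominant source (|c1| >= |c2|)")
  structure(list(c1 = c1, c2 = c2, label = label), class = "nm_condition")
}

#' The four task conditions at representative coherences
#'
#' Leftward-coded encodings used for the parameter sweeps: CON splits
#' `c_high` into same-sign `c_low` and `c_high - c_low`; CON_BSL is
#' `c_high` alone; INC opposes `c_high` and `-(c_high - c_low)` (net
#' `c_low`); INC_BSL is `c_low` alone.
#'
#' @param c_high,c_low Representative combined coherence levels (defaults
#'   20% and 15%).
#' @return A named list of four [nm_condition()] objects.
#' @export
nm_task_conditions <- function(c_high = 0.20, c_low = 0.15) {
  con <- sort(c(c_low, c_high - c_low), decreasing = TRUE)
  list(
    CON = nm_condition(con[1], con[2], "CON"),
    CON_BSL = nm_condition(c_high, 0, "CON_BSL"),
    INC = nm_condition(c_high, -(c_high - c_low), "INC"),
    INC_BSL = nm_condition(c_low, 0, "INC_BSL")
  )
}

#' Deterministic input currents
#'
#' Evaluates the two input currents of the extended model.  `beta` is applied
#' only when the condition is the incongruent double-source condition
#' (`label == "INC"`); otherwise the background term uses `beta = 1`.
#'
#' @param p An [nm_params()] object.
#' @param cond An [nm_condition()] object.
#' @return Named numeric vector `c(I_L, I_R)` in nA.
#' @examples
#' p <- nm_params(alpha = 0.7, beta = 1.018)
#' input_currents(p, nm_condition(0.20, -0.05, "INC"))["I_L"]  # 0.347253
#' @export
input_currents <- function(p, cond) {
  stopifnot(inherits(p, "nm_params"), inherits(cond, "nm_condition"))
  b <- if (cond$label == "INC") p$beta else 1
  sel <- function(s1, s2)
    p$J_ext * (p$alpha * p$mu * (1 + s1) + (1 - p$alpha) * p$mu * (1 + s2))
  c(I_L = sel(cond$c1, cond$c2) + b * p$I_0,
    I_R = sel(-cond$c1, -cond$c2) + b * p$I_0)
}

#' Simulate neural-mass trials
#'
#' Integrates the two-variable reduced dynamics (Euler-Maruyama, symmetric
#' initial gating S = 0.1, OU noise currents) until one population rate
#' crosses the decision threshold or the deadline elapses.  The returned RT
#' includes the fixed non-decision offset `ndt`.
#'
#' @param p An [nm_params()] object.
#' @param cond An [nm_condition()] object.
#' @param n Number of trials.
#' @param seed Optional integer seed.
#' @return A data frame with `choice` (`"L"`, `"R"`, `"none"`) and `rt`
#'   (seconds, `NA` on timeout).
#' @export
simulate_nm_trial <- function(p, cond, n = 1, seed = NULL) {
  stopifnot(inherits(p, "nm_params"), inherits(cond, "nm_condition"))
  if (!is.null(seed)) set.seed(seed)
  I <- input_currents(p, cond)
  res <- simulate_nm_cpp(as.integer(n), I[["I_L"]], I[["I_R"]],
                         p$J_self, p$J_cross, p$a_H, p$b_H, p$d_H,
                         p$gamma, p$tau_S, p$sigma_noise, p$tau_noise,
                         p$threshold, p$ndt, p$dt, p$t_max)
  data.frame(choice = c("R", "none", "L")[res$choice + 2L], rt = res$rt,
             stringsAsFactors = FALSE)
}

#' Accuracy, mean RT and timeout rate of one condition
#'
#' Runs `n_trials` simulations of a condition and aggregates completed
#' trials.  The correct response is the direction of the net combined
#' coherence (`sign(c1 + c2)`); accuracy and mean RT pool correct and error
#' trials that completed, timeouts are reported separately.  Monte-Carlo
#' standard errors are returned for use in the indeterminacy guard of
#' [qualitative_pattern()].
#'
#' @param p An [nm_params()] object.
#' @param cond An [nm_condition()] object.
#' @param n_trials Number of simulated trials (default 5000).
#' @param seed Optional integer seed.
#' @return A list: `accuracy`, `mean_rt`, `timeout_rate`, `n_completed`,
#'   `se_accuracy`, `se_rt`.
#' @export
condition_performance <- function(p, cond, n_trials = 5000, seed = NULL) {
  if (n_trials < 1) stop("'n_trials' must be at least 1")
  sim <- simulate_nm_trial(p, cond, n = n_trials, seed = seed)
  done <- sim$choice != "none"
  correct_side <- if (cond$c1 + cond$c2 >= 0) "L" else "R"
  corr <- sim$choice[done] == correct_side
  acc <- mean(corr)
  rts <- sim$rt[done]
  list(accuracy = acc,
       mean_rt = mean(rts),
       timeout_rate = mean(!done),
       n_completed = sum(done),
       se_accuracy = sqrt(acc * (1 - acc) / max(1, sum(done))),
       se_rt = sd(rts) / sqrt(max(1, sum(done))))
}

#' Qualitative behavioural pattern of one parameter cell
#'
#' TRUE when all four directional inequalities observed behaviourally hold in
#' the simulated performance: the congruent double-source condition is less
#' accurate and slower than its baseline, and the incongruent double-source
#' condition is less accurate and faster than its baseline.  Inequalities
#' whose margin is below `guard_z` Monte-Carlo standard errors are treated as
#' indeterminate and return `NA`.
#'
#' @param perf Named list of [condition_performance()] results for `CON`,
#'   `CON_BSL`, `INC`, `INC_BSL`.
#' @param guard_z Indeterminacy guard in units of the combined MC standard
#'   error (0 disables the guard).
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate).
#' @export
qualitative_pattern <- function(perf, guard_z = 0) {
  miss <- setdiff(.task_conditions, names(perf))
  if (length(miss)) stop("missing condition(s): ", paste(miss, collapse = ", "))
  comp <- function(a, b, field, sefield) {
    margin <- b[[field]] - a[[field]]
    se <- sqrt(a[[sefield]]^2 + b[[sefield]]^2)
    if (guard_z > 0 && abs(margin) < guard_z * se) return(NA)
    margin > 0
  }
  checks <- c(
    comp(perf$CON, perf$CON_BSL, "accuracy", "se_accuracy"),   # CON less accurate
    comp(perf$CON_BSL, perf$CON, "mean_rt", "se_rt"),          # CON slower
    comp(perf$INC, perf$INC_BSL, "accuracy", "se_accuracy"),   # INC less accurate
    comp(perf$INC, perf$INC_BSL, "mean_rt", "se_rt")           # INC faster
  )
  if (any(is.na(checks))) {
    if (all(checks[!is.na(checks)])) return(NA)  # plausible but unresolved
    return(FALSE)
  }
  all(checks)
}

#' Sweep the (alpha, beta) parameter plane
#'
#' For every grid cell, simulates the four task conditions (`beta` applied to
#' the incongruent double-source condition only) and records the
#' baseline-minus-double differences in accuracy and mean RT together with
#' the qualitative-pattern classification.
#'
#' @param p_base An [nm_params()] object providing all non-swept constants.
#' @param alphas,betas Grid values (defaults span 0.1-0.9 and 0.98-1.02).
#' @param n_trials_per_cond Simulated trials per condition per cell.
#' @param c_high,c_low Representative coherences.
#' @param guard_z Indeterminacy guard passed to [qualitative_pattern()].
#' @param seed Integer seed (each cell gets a derived sub-seed).
#' @return An object of class `nm_sweep`: a data frame with one row per cell
#'   (`alpha`, `beta`, per-condition accuracy and RT, `d_acc_con`,
#'   `d_rt_con`, `d_acc_inc`, `d_rt_inc` as baseline minus double, and
#'   `qualifies`).
#' @export
sweep_alpha_beta <- function(p_base = nm_params(),
                             alphas = seq(0.1, 0.9, length.out = 5),
                             betas = seq(0.98, 1.02, length.out = 5),
                             n_trials_per_cond = 5000,
                             c_high = 0.20, c_low = 0.15,
                             guard_z = 2, seed = 1L) {
  conds <- nm_task_conditions(c_high, c_low)
  grid <- expand.grid(alpha = alphas, beta = betas)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max %/% 2, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    p <- p_base
    p$alpha <- grid$alpha[k]
    p$beta <- grid$beta[k]
    set.seed(cell_seeds[k])
    perf <- lapply(conds, function(cd)
      condition_performance(p, cd, n_trials = n_trials_per_cond))
    data.frame(
      alpha = grid$alpha[k], beta = grid$beta[k],
      acc_con = perf$CON$accuracy, acc_con_bsl = perf$CON_BSL$accuracy,
      acc_inc = perf$INC$accuracy, acc_inc_bsl = perf$INC_BSL$accuracy,
      rt_con = perf$CON$mean_rt, rt_con_bsl = perf$CON_BSL$mean_rt,
      rt_inc = perf$INC$mean_rt, rt_inc_bsl = perf$INC_BSL$mean_rt,
      d_acc_con = perf$CON_BSL$accuracy - perf$CON$accuracy,
      d_rt_con = perf$CON_BSL$mean_rt - perf$CON$mean_rt,
      d_acc_inc = perf$INC_BSL$accuracy - perf$INC$accuracy,
      d_rt_inc = perf$INC_BSL$mean_rt - perf$INC$mean_rt,
      qualifies = qualitative_pattern(perf, guard_z = guard_z)
    )
  })
  structure(do.call(rbind, rows), class = c("nm_sweep", "data.frame"))
}

#' @export
print.nm_sweep <- function(x, ...) {
  cat(sprintf("Neural-mass (alpha, beta) sweep: %d cells, %d qualifying, %d indeterminate\n",
              nrow(x), sum(x$qualifies %in% TRUE), sum(is.na(x$qualifies))))
  print.data.frame(head(as.data.frame(x)[, c("alpha", "beta", "d_acc_con",
                                             "d_rt_con", "d_acc_inc",
                                             "d_rt_inc", "qualifies")], 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.nm_sweep <- function(x, ...) {
  al <- sort(unique(x$alpha)); be <- sort(unique(x$beta))
  z <- matrix(NA_real_, length(al), length(be))
  for (k in seq_len(nrow(x)))
    z[match(x$alpha[k], al), match(x$beta[k], be)] <-
      as.numeric(x$qualifies[k] %in% TRUE)
  image(al, be, z, xlab = expression(alpha), ylab = expression(beta),
        main = "Qualifying region", ...)
  abline(v = 0.5, h = 1, lty = 2)
  invisible(x)
}
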