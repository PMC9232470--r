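# Fixed-step n-down/1-up staircases on log10 coherence.  With an up step of
# 0.1 log units and a down step of 0.074 (ratio 0.74), the two-down/one-up
# rule converges near 74% correct and the three-down/one-up rule near 83%
# in a 2AFC task; these asymptotes are rule- and step-determined, not
# observer-determined.

#' Initialise a staircase
#'
#' @param rule Down rule `n` of the n-down/1-up staircase (2 or 3).
#' @param start_coherence Initial coherence (fraction); default the
#'   supra-threshold 31.6%.
#' @param up_step,down_step Step sizes in log10 units applied after an error
#'   (up) or after `rule` consecutive correct responses (down).
#' @return A `staircase_state` list: `rule`, `log10_coherence`, `up_step`,
#'   `down_step`, `consecutive_correct`, `last_move` (`"up"|"down"|"none"`),
#'   `reversal_levels` (coherences at direction changes) and `trial_count`.
#' @export
staircase_init <- function(rule = 2, start_coherence = 0.316,
                           up_step = 0.1, down_step = 0.074) {
  if (!rule %in% c(2, 3)) stop("'rule' must be 2 or 3")
  if (start_coherence <= 0 || start_coherence > 1)
    stop("'start_coherence' must be in (0, 1]")
  structure(list(
    rule = as.integer(rule),
    log10_coherence = log10(start_coherence),
    up_step = up_step, down_step = down_step,
    consecutive_correct = 0L,
    last_move = "none",
    reversal_levels = numeric(0),
    trial_count = 0L
  ), class = "staircase_state")
}

#' Advance a staircase by one trial
#'
#' An error moves the level up by `up_step` and resets the run counter; the
#' `rule`-th consecutive correct response moves it down by `down_step` and
#' resets the counter; other correct responses only increment the counter.
#' A reversal is recorded when the direction of a level change differs from
#' the previous change (the level *before* the new move is appended to
#' `reversal_levels`); the initial run before the first direction change is
#' not a reversal.  Coherence is clipped at 100% (log10 = 0), with the run
#' counter reset on clipping.
#'
#' @param state A `staircase_state`.
#' @param correct Logical: was the response correct?
#' @return The updated state.
#' @examples
#' s <- staircase_init(2)
#' s <- staircase_step(s, FALSE)     # error: 31.6% -> 39.8%
#' 10^s$log10_coherence
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  state$trial_count <- state$trial_count + 1L
  move <- NULL
  if (!correct) {
    move <- "up"
    new_level <- state$log10_coherence + state$up_step
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= state$rule) {
      move <- "down"
      new_level <- state$log10_coherence - state$down_step
      state$consecutive_correct <- 0L
    }
  }
  if (!is.null(move)) {
    if (state$last_move != "none" && move != state$last_move)
      state$reversal_levels <- c(state$reversal_levels,
                                 10^state$log10_coherence)
    if (new_level > 0) {           # ceiling: coherence cannot exceed 100%
      new_level <- 0
      state$consecutive_correct <- 0L
    }
    state$log10_coherence <- new_level
    state$last_move <- move
  }
  state
}

#' Logistic ideal observer in log coherence
#'
#' A smooth 2AFC psychometric function
#' `P(correct | c) = 0.5 + 0.5 * plogis(slope * log10(c / threshold75))`,
#' strictly increasing in coherence, equal to 0.75 at `threshold75`, with
#' zero lapse (range (0.5, 1)).
#'
#' @param threshold75 Coherence at which the observer is 75% correct.
#' @param slope Logistic slope in 1/log10 units.
#' @return A function mapping coherence to P(correct).
#' @export
logistic_observer <- function(threshold75 = 0.12, slope = 8) {
  force(threshold75); force(slope)
  function(coherence) 0.5 + 0.5 * plogis(slope * log10(coherence / threshold75))
}

run_one_staircase <- function(rule, observer, stop_reversals, start_coherence,
                              up_step, down_step, max_trials) {
  state <- staircase_init(rule, start_coherence, up_step, down_step)
  coh_hist <- numeric(max_trials)
  cor_hist <- logical(max_trials)
  rev_hist <- logical(max_trials)
  n <- 0L
  while (length(state$reversal_levels) < stop_reversals && n < max_trials) {
    n <- n + 1L
    coh <- 10^state$log10_coherence
    p <- observer(coh)
    if (!is.finite(p) || p < 0.5 || p > 1)
      stop("observer must return P(correct) in [0.5, 1]")
    correct <- runif(1) < p
    nrev <- length(state$reversal_levels)
    state <- staircase_step(state, correct)
    coh_hist[n] <- coh
    cor_hist[n] <- correct
    rev_hist[n] <- length(state$reversal_levels) > nrev
  }
  degenerate <- length(state$reversal_levels) < stop_reversals
  revs <- state$reversal_levels
  k <- stop_reversals - 1L
  threshold <- if (length(revs) >= k && k >= 1)
    mean(revs[(length(revs) - k + 1L):length(revs)]) else NA_real_
  list(threshold = threshold,
       reversal_levels = revs,
       degenerate = degenerate,
       history = data.frame(trial = seq_len(n), coherence = coh_hist[seq_len(n)],
                            correct = cor_hist[seq_len(n)],
                            reversal = rev_hist[seq_len(n)]))
}

#' Run a staircase against a simulated observer
#'
#' Runs an n-down/1-up staircase until `stop_reversals` reversals have
#' occurred; the threshold is the mean of the coherences at the last
#' `stop_reversals - 1` reversals (the conventional discard of the first
#' reversal).  Runs that exhaust `max_trials` before reaching the reversal
#' count (e.g. with a deterministic, always-correct observer, which descends
#' monotonically) are flagged `degenerate` with `threshold = NA`.
#'
#' @param rule 2 or 3 (n-down/1-up).
#' @param observer Function mapping coherence to P(correct) in `[0.5, 1]`,
#'   e.g. [logistic_observer()].
#' @param stop_reversals Reversal count at termination (>= 2; default 10).
#' @param seed Optional integer seed.
#' @param start_coherence,up_step,down_step As in [staircase_init()].
#' @param max_trials Safety cap on trial count.
#' @return A list with `threshold` (coherence), `reversal_levels`,
#'   `degenerate`, and a per-trial `history` data frame
#'   (`trial`, `coherence`, `correct`, `reversal`).
#' @examples
#' r <- run_staircase(2, logistic_observer(0.12, 8), seed = 1)
#' r$threshold
#' @export
run_staircase <- function(rule, observer, stop_reversals = 10, seed = NULL,
                          start_coherence = 0.316, up_step = 0.1,
                          down_step = 0.074,
                          max_trials = 200L * stop_reversals) {
  if (stop_reversals < 2) stop("'stop_reversals' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  run_one_staircase(rule, observer, stop_reversals, start_coherence,
                    up_step, down_step, max_trials)
}

#' Run the interleaved pair of staircases
#'
#' The dual calibration routine: a two-down/one-up staircase (targeting the
#' low coherence `c_low`, ~74% correct) and a three-down/one-up staircase
#' (targeting the high coherence `c_high`, ~83% correct) both start at 31.6%
#' coherence and are strictly alternated trial by trial (a staircase that
#' has finished is skipped); each terminates after `stop_reversals`
#' reversals.  Strict alternation is used for reproducibility; set
#' `schedule = "random"` for random mixing.
#'
#' @inheritParams run_staircase
#' @param schedule `"alternate"` (default) or `"random"`.
#' @return A list with `c_low` and `c_high` (the two thresholds) and
#'   `histories` (per-rule trial histories with a `staircase_id` column).
#' @export
run_interleaved <- function(observer, stop_reversals = 10, seed = NULL,
                            schedule = c("alternate", "random"),
                            start_coherence = 0.316, up_step = 0.1,
                            down_step = 0.074,
                            max_trials = 200L * stop_reversals) {
  schedule <- match.arg(schedule)
  if (!is.null(seed)) set.seed(seed)
  states <- list(staircase_init(2, start_coherence, up_step, down_step),
                 staircase_init(3, start_coherence, up_step, down_step))
  hist <- list(list(), list())
  done <- c(FALSE, FALSE)
  turn <- 1L
  total <- 0L
  while (!all(done) && total < 2L * max_trials) {
    k <- if (schedule == "alternate") turn else sample(1:2, 1)
    if (done[k]) k <- if (k == 1L) 2L else 1L
    st <- states[[k]]
    coh <- 10^st$log10_coherence
    p <- observer(coh)
    if (!is.finite(p) || p < 0.5 || p > 1)
      stop("observer must return P(correct) in [0.5, 1]")
    correct <- runif(1) < p
    nrev <- length(st$reversal_levels)
    st <- staircase_step(st, correct)
    states[[k]] <- st
    hist[[k]][[length(hist[[k]]) + 1L]] <-
      c(coherence = coh, correct = as.numeric(correct),
        reversal = as.numeric(length(st$reversal_levels) > nrev))
    done[k] <- length(st$reversal_levels) >= stop_reversals
    turn <- if (turn == 1L) 2L else 1L
    total <- total + 1L
  }
  thr <- function(st) {
    revs <- st$reversal_levels
    k <- stop_reversals - 1L
    if (length(revs) >= k) mean(revs[(length(revs) - k + 1L):length(revs)])
    else NA_real_
  }
  mk_hist <- function(k) {
    m <- do.call(rbind, hist[[k]])
    data.frame(trial = seq_len(nrow(m)), staircase_id = k,
               rule = c(2L, 3L)[k], coherence = m[, "coherence"],
               correct = as.logical(m[, "correct"]),
               reversal = as.logical(m[, "reversal"]))
  }
  list(c_low = thr(states[[1]]), c_high = thr(states[[2]]),
       histories = rbind(mk_hist(1), mk_hist(2)))
}

#' Asymptotic accuracy of a staircase rule
#'
#' Runs a staircase far past its usual termination (`n_reversals` reversals,
#' at least 200), averages the late reversal levels (the second half,
#' discarding the convergence transient) in the staircase's own step domain
#' (log10 coherence, i.e. the geometric mean - the equilibrium of a
#' fixed-step random walk is defined on its step scale), and returns the
#' observer's true P(correct) at that converged level.  Over many replicates this
#' estimates the asymptotic percent-correct the rule targets (~74% for
#' 2-down/1-up, ~83% for 3-down/1-up with the 0.074/0.1 steps), which is a
#' property of the rule and step ratio, not of the observer's slope.
#'
#' @inheritParams run_staircase
#' @param n_reversals Number of reversals to run (>= 200).
#' @return A list with `accuracy` (true P(correct) at the converged level),
#'   `converged_coherence`, and `n_trials`.
#' @export
asymptotic_accuracy <- function(rule, observer, n_reversals = 200,
                                seed = NULL, start_coherence = 0.316,
                                up_step = 0.1, down_step = 0.074) {
  if (n_reversals < 200) stop("'n_reversals' must be at least 200")
  if (!is.null(seed)) set.seed(seed)
  r <- run_one_staircase(rule, observer, n_reversals, start_coherence,
                         up_step, down_step, max_trials = 400L * n_reversals)
  revs <- r$reversal_levels
  late <- revs[(floor(length(revs) / 2) + 1L):length(revs)]
  coh <- 10^mean(log10(late))
  list(accuracy = observer(coh), converged_coherence = coh,
       n_trials = nrow(r$history))
}
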