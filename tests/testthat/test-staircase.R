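# Fixed-step n-down/1-up staircases: step arithmetic, reversal bookkeeping,
# convergence and the equilibrium property of the 74%-targeting rule.

test_that("single steps follow the forced arithmetic", {
  s <- staircase_init(2)
  expect_equal(s$log10_coherence, log10(0.316))
  # an error moves up one 0.1 log step
  s1 <- staircase_step(s, FALSE)
  expect_equal(s1$log10_coherence, log10(0.316) + 0.1)
  expect_equal(10^s1$log10_coherence, 0.398, tolerance = 1e-3)
  # two consecutive correct move down one 0.074 step
  s2 <- staircase_step(staircase_step(s, TRUE), TRUE)
  expect_equal(s2$log10_coherence, log10(0.316) - 0.074)
  expect_equal(10^s2$log10_coherence, 0.267, tolerance = 5e-3)
  # one correct alone does not move the level
  s3 <- staircase_step(s, TRUE)
  expect_equal(s3$log10_coherence, s$log10_coherence)
  expect_equal(s3$consecutive_correct, 1L)
})

test_that("a reversal is recorded at the turning level", {
  s <- staircase_init(2)
  # down, down, then an error (up): exactly one reversal at the turning level
  for (i in 1:4) s <- staircase_step(s, TRUE)
  expect_length(s$reversal_levels, 0)
  lvl_before_up <- 10^s$log10_coherence
  s <- staircase_step(s, FALSE)
  expect_length(s$reversal_levels, 1)
  expect_equal(s$reversal_levels[1], lvl_before_up)
})

test_that("coherence is clipped at 100%", {
  s <- staircase_init(2, start_coherence = 0.9)
  for (i in 1:5) s <- staircase_step(s, FALSE)
  expect_equal(s$log10_coherence, 0)
  expect_equal(10^s$log10_coherence, 1)
})

test_that("runs terminate at the reversal count with a sane threshold", {
  obs <- logistic_observer(0.12, 8)
  r <- run_staircase(2, obs, stop_reversals = 10, seed = 4)
  expect_length(r$reversal_levels, 10)
  expect_equal(r$threshold, mean(r$reversal_levels[2:10]))
  expect_false(r$degenerate)
  expect_true(all(r$history$coherence > 0 & r$history$coherence <= 1))
  expect_gte(r$threshold, min(r$history$coherence))
  expect_lte(r$threshold, max(r$history$coherence))
  expect_equal(sum(r$history$reversal), 10)
  # determinism
  r2 <- run_staircase(2, obs, stop_reversals = 10, seed = 4)
  expect_identical(r$history, r2$history)
})

test_that("degenerate and invalid observers are handled", {
  always_right <- function(coherence) 1
  r <- run_staircase(2, always_right, stop_reversals = 10, seed = 1,
                     max_trials = 500)
  expect_true(r$degenerate)
  expect_true(is.na(r$threshold))
  # monotone descent: levels never increase
  expect_true(all(diff(r$history$coherence) <= 0))
  expect_error(run_staircase(2, function(c) 0.3, seed = 1))
  expect_error(run_staircase(2, function(c) 1.2, seed = 1))
  expect_error(run_staircase(2, logistic_observer(), stop_reversals = 1))
})

test_that("the 2-down staircase converges near the observer's 75% point", {
  obs <- logistic_observer(0.12, 8)
  set.seed(10)
  thr <- vapply(1:200, function(i)
    run_staircase(2, obs, stop_reversals = 10)$threshold, 0)
  expect_gt(median(thr), 0.12 - 0.04)
  expect_lt(median(thr), 0.12 + 0.04)
})

test_that("interleaved staircases give c_low below c_high", {
  obs <- logistic_observer(0.12, 8)
  set.seed(2)
  reps <- t(vapply(1:100, function(i) {
    r <- run_interleaved(obs)
    c(r$c_low, r$c_high)
  }, c(0, 0)))
  expect_lt(median(reps[, 1]), median(reps[, 2]))
  # reproducible histories
  r1 <- run_interleaved(obs, seed = 6)
  r2 <- run_interleaved(obs, seed = 6)
  expect_identical(r1$histories, r2$histories)
  # both staircases hit their reversal counts
  expect_equal(sum(r1$histories$reversal[r1$histories$rule == 2]), 10)
  expect_equal(sum(r1$histories$reversal[r1$histories$rule == 3]), 10)
})

test_that("a flat 75% observer leaves the 2-down rule near equilibrium", {
  flat <- function(coherence) 0.75
  set.seed(8)
  s <- staircase_init(2, start_coherence = 0.05)
  start <- s$log10_coherence
  n_moves <- 0
  for (i in 1:600) {
    lvl <- s$log10_coherence
    s <- staircase_step(s, runif(1) < 0.75)
    if (s$log10_coherence != lvl) n_moves <- n_moves + 1
  }
  drift_per_move <- (s$log10_coherence - start) / n_moves
  expect_lt(abs(drift_per_move), 0.02)   # small relative to the 0.1 step
})

test_that("asymptotic level is rule-determined, not slope-determined", {
  set.seed(3)
  shallow <- mean(vapply(1:15, function(i)
    asymptotic_accuracy(2, logistic_observer(0.12, 8), 200)$accuracy, 0))
  steep <- mean(vapply(1:15, function(i)
    asymptotic_accuracy(2, logistic_observer(0.12, 16), 200)$accuracy, 0))
  expect_lt(abs(shallow - steep), 0.03)
  expect_error(asymptotic_accuracy(2, logistic_observer(), n_reversals = 50))
})
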