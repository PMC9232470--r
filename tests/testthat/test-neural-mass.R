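# Extended two-population attractor model: input-current algebra, trial
# dynamics, and the qualitative-pattern classification.

test_that("input currents evaluate the weighted-sum formula exactly", {
  p <- nm_params(alpha = 0.7, beta = 1.018)
  I <- input_currents(p, nm_condition(0.20, -0.05, "INC"))
  expect_equal(unname(I["I_L"]),
               5.2e-4 * (0.7 * 35 * 1.2 + 0.3 * 35 * 0.95) + 1.018 * 0.321)
  expect_equal(unname(I["I_L"]), 0.347253)
  # beta applies only to the incongruent double-source condition
  p2 <- nm_params(alpha = 0.7, beta = 1.018)
  I_con <- input_currents(p2, nm_condition(0.15, 0.05, "CON"))
  p3 <- nm_params(alpha = 0.7, beta = 1)
  expect_equal(I_con, input_currents(p3, nm_condition(0.15, 0.05, "CON")))
})

test_that("input currents collapse and mirror as the algebra dictates", {
  p <- nm_params(alpha = 0.5)
  # alpha = 0.5 with equal coherences reduces to a single source at c
  I2 <- input_currents(p, nm_condition(0.2, 0.2, "CON"))
  expect_equal(unname(I2["I_L"]), p$J_ext * p$mu * 1.2 + p$I_0)
  # negating both coherences swaps left and right exactly
  pa <- nm_params(alpha = 0.65)
  Ia <- input_currents(pa, nm_condition(0.2, -0.05, "INC"))
  Ib <- input_currents(pa, nm_condition(-0.2, 0.05, "INC"))
  expect_equal(unname(Ia["I_L"]), unname(Ib["I_R"]))
  expect_equal(unname(Ia["I_R"]), unname(Ib["I_L"]))
  # at alpha = 0.5 the congruent split is indistinguishable from its baseline
  I_con <- input_currents(p, nm_condition(0.15, 0.05, "CON"))
  I_bsl <- input_currents(p, nm_condition(0.20, 0.00, "CON_BSL"))
  expect_equal(I_con, I_bsl)
})

test_that("parameter and condition constructors validate", {
  expect_error(nm_params(alpha = 1.2))
  expect_error(nm_params(dt = 0.002))
  expect_error(nm_params(I_0 = -1))
  expect_error(nm_condition(0.05, 0.2, "CON"))
  expect_output(print(nm_params()), "alpha")
})

test_that("symmetric inputs yield chance choices", {
  p <- nm_params()
  sim <- simulate_nm_trial(p, nm_condition(0, 0, "CON_BSL"), n = 4000,
                           seed = 5)
  done <- sim$choice != "none"
  pL <- mean(sim$choice[done] == "L")
  expect_lt(abs(pL - 0.5), 3 * sqrt(0.25 / sum(done)))
})

test_that("accuracy grows with net evidence and mirrors under sign flips", {
  p <- nm_params()
  hard <- condition_performance(p, nm_condition(0.15, 0, "INC_BSL"),
                                n_trials = 2500, seed = 11)
  easy <- condition_performance(p, nm_condition(0.60, 0, "INC_BSL"),
                                n_trials = 2500, seed = 12)
  expect_gt(easy$accuracy, hard$accuracy)
  # mirrored condition gives mirrored choice frequencies
  pa <- nm_params(alpha = 0.7, beta = 1.018)
  left <- condition_performance(pa, nm_condition(0.2, -0.05, "INC"),
                                n_trials = 2500, seed = 13)
  right <- condition_performance(pa, nm_condition(-0.2, 0.05, "INC"),
                                 n_trials = 2500, seed = 14)
  se <- sqrt(2 * left$accuracy * (1 - left$accuracy) / 2500)
  expect_lt(abs(left$accuracy - right$accuracy), 4 * se + 1e-9)
})

test_that("condition performance is deterministic under a fixed seed", {
  p <- nm_params(alpha = 0.7, beta = 1.018)
  a <- condition_performance(p, nm_condition(0.2, -0.05, "INC"),
                             n_trials = 500, seed = 3)
  b <- condition_performance(p, nm_condition(0.2, -0.05, "INC"),
                             n_trials = 500, seed = 3)
  expect_identical(a, b)
})

test_that("raising the background input trades accuracy for speed", {
  base <- nm_params(alpha = 0.7, beta = 1)
  fast <- nm_params(alpha = 0.7, beta = 1.02)
  cond <- nm_condition(0.2, -0.05, "INC")
  perf0 <- condition_performance(base, cond, n_trials = 3000, seed = 21)
  perf1 <- condition_performance(fast, cond, n_trials = 3000, seed = 22)
  expect_lt(perf1$mean_rt, perf0$mean_rt)
  expect_lt(perf1$accuracy, perf0$accuracy)
})

test_that("qualitative pattern implements the four inequalities with a guard", {
  mk <- function(acc, rt, se_a = 1e-6, se_r = 1e-6)
    list(accuracy = acc, mean_rt = rt, se_accuracy = se_a, se_rt = se_r)
  good <- list(CON = mk(0.90, 1.4), CON_BSL = mk(0.95, 1.2),
               INC = mk(0.70, 1.1), INC_BSL = mk(0.75, 1.3))
  expect_true(qualitative_pattern(good))
  bad <- good
  bad$INC$mean_rt <- 1.5            # incongruent no longer faster
  expect_false(qualitative_pattern(bad, guard_z = 2))
  marginal <- good
  marginal$CON$accuracy <- 0.9499
  marginal$CON$se_accuracy <- 0.01
  marginal$CON_BSL$se_accuracy <- 0.01
  expect_true(is.na(qualitative_pattern(marginal, guard_z = 2)))
  expect_error(qualitative_pattern(good[-1]))
})

test_that("no mechanism means no pattern at equal weights and unit beta", {
  p <- nm_params(alpha = 0.5, beta = 1)
  conds <- nm_task_conditions()
  set.seed(33)
  perf <- lapply(conds, function(cd)
    condition_performance(p, cd, n_trials = 2500))
  expect_false(isTRUE(qualitative_pattern(perf, guard_z = 2)))
})
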