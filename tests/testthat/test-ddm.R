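# Drift-diffusion primitives: closed-form oracles, series density, simulator
# agreement and the outlier-mixture likelihood.

test_that("closed-form choice probability and mean decision time behave", {
  expect_equal(ddm_choice_probability(0, 3), 0.5)
  expect_equal(ddm_choice_probability(1, 2), 1 / (1 + exp(-2)))
  # depends on the product v*a only
  expect_equal(ddm_choice_probability(2, 1), ddm_choice_probability(1, 2))
  expect_equal(ddm_mean_decision_time(1, 2), (2 / 2) * tanh(1))
  expect_equal(ddm_mean_decision_time(0, 2), 1)  # a^2 / 4 limit
  expect_error(ddm_choice_probability(1, 0))
  expect_error(ddm_choice_probability(1, -1))
})

test_that("accuracy and speed are monotone in drift and boundary", {
  vs <- seq(0.2, 3, length.out = 8)
  as_ <- seq(0.5, 3, length.out = 8)
  # in v at fixed a: accuracy up, mean decision time down
  expect_true(all(diff(ddm_choice_probability(vs, 1.5)) > 0))
  expect_true(all(diff(ddm_mean_decision_time(vs, 1.5)) < 0))
  # in a at fixed v: both accuracy and mean decision time up
  expect_true(all(diff(ddm_choice_probability(1, as_)) > 0))
  expect_true(all(diff(ddm_mean_decision_time(1, as_)) > 0))
})

test_that("wfpt density normalises and splits mass consistently", {
  for (pars in list(c(v = 1, a = 2), c(v = 0.5, a = 1.2), c(v = 2.5, a = 0.8))) {
    up <- integrate(function(t) wfpt_density(t, pars["v"], pars["a"]),
                    0, Inf, rel.tol = 1e-9)$value
    lo <- integrate(function(t) wfpt_density(t, pars["v"], pars["a"],
                                             boundary = "lower"),
                    0, Inf, rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-6)
    expect_equal(up, unname(ddm_choice_probability(pars["v"], pars["a"])),
                 tolerance = 1e-6)
  }
  # zero mass before the non-decision time
  expect_equal(wfpt_density(c(0.1, 0.29), 1, 2, ter = 0.3), c(0, 0))
})

test_that("simulator agrees with the analytic absorption law", {
  n <- 20000
  for (pars in list(c(v = 0, a = 2), c(v = 1, a = 2), c(v = 2, a = 1))) {
    sim <- simulate_ddm(n, pars["v"], pars["a"], ter = 0, t_max = 30, seed = 7)
    p_true <- unname(ddm_choice_probability(pars["v"], pars["a"]))
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(mean(sim$boundary == "upper") - p_true), 4 * se)
    dt_true <- unname(ddm_mean_decision_time(pars["v"], pars["a"]))
    expect_lt(abs(mean(sim$rt) - dt_true), 0.015)
  }
})

test_that("non-decision time shifts RT additively, leaving choices unchanged", {
  s1 <- simulate_ddm(2000, 1, 2, ter = 0.3, t_max = 30, seed = 42)
  s2 <- simulate_ddm(2000, 1, 2, ter = 0.5, t_max = 30, seed = 42)
  expect_identical(s1$boundary, s2$boundary)
  expect_equal(s2$rt, s1$rt + 0.2)
})

test_that("simulator rejects invalid steps and parameters", {
  expect_error(simulate_ddm(10, 1, 2, dt = 0))
  expect_error(simulate_ddm(10, 1, 2, dt = 0.01))
  expect_error(simulate_ddm(10, 1, -1))
  expect_error(simulate_ddm(10, 1, 2, ter = 5, t_max = 4))
})

test_that("mixture likelihood handles outliers and impossible data", {
  # rt below Ter: impossible under the pure Wiener model
  expect_identical(ddm_trial_loglik(0.1, TRUE, 1, 2, 0.3, outlier_frac = 0),
                   -Inf)
  # pure outlier branch: log(q / (2 * t_max))
  expect_equal(ddm_trial_loglik(0.1, TRUE, 1, 2, 0.3, outlier_frac = 0.05,
                                t_max = 4),
               log(0.05 / 8))
  # mixture equals its definition away from Ter
  ll <- ddm_trial_loglik(1.1, TRUE, 1, 2, 0.3, outlier_frac = 0.05, t_max = 4)
  expect_equal(ll, log(0.95 * wfpt_density(1.1, 1, 2, ter = 0.3) + 0.05 / 8))
  expect_error(ddm_trial_loglik(5, TRUE, 1, 2, 0.3, t_max = 4))
  expect_error(ddm_trial_loglik(1, TRUE, 1, 2, 0.3, outlier_frac = 1))
})

test_that("summed likelihood is maximised near the generating drift", {
  sim <- simulate_ddm(4000, 1, 1.5, ter = 0.3, seed = 13)
  done <- sim$boundary != "none"
  rt <- sim$rt[done]
  corr <- sim$boundary[done] == "upper"
  grid <- seq(0.4, 1.6, by = 0.05)
  ll <- vapply(grid, function(v)
    sum(ddm_trial_loglik(rt, corr, v, 1.5, 0.3, outlier_frac = 0.05)), 0)
  expect_lt(abs(grid[which.max(ll)] - 1), 0.15)
})

test_that("ddm_params validates its arguments", {
  p <- ddm_params(1, 2, 0.3)
  expect_s3_class(p, "ddm_params")
  expect_error(ddm_params(1, 0))
  expect_error(ddm_params(1, 2, -0.1))
  expect_output(print(p), "v = 1")
})
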