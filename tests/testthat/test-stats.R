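# Preprocessing filters, condition summaries, the mixed ANOVA and the paired
# t-test power computation.

toy_trials <- function() {
  data.frame(
    subject_id = 1, group_angle = 20, block = 1, trial = 1:10,
    condition = "CON", c1 = 0.15, c2 = 0.05, direction = "left",
    choice = c(rep("left", 7), "left", "left", "none"),
    rt = c(runif(7, 0.4, 1.5), 0.2, 0.21, NA),
    is_valid = c(rep(TRUE, 9), FALSE),
    stringsAsFactors = FALSE
  )
}

test_that("fast guesses and non-responses are removed with exact counts", {
  set.seed(1)
  pp <- preprocess(toy_trials())
  expect_equal(nrow(pp$trials), 7)
  expect_equal(pp$report$n_fast, 2)
  expect_equal(pp$report$n_no_response, 1)
  expect_equal(pp$report$removed_fraction, 0.30)
})

test_that("low block-pair accuracy excludes the subject", {
  good <- generate_cohort(cohort_spec(n_subjects = 2, seed = 3))$trials
  bad <- good[good$subject_id == 2, ]
  # force exactly 50% accuracy in blocks 1-2 for subject 2
  sel <- which(bad$block <= 2)
  opp <- ifelse(bad$direction == "left", "right", "left")
  bad$choice[sel] <- ifelse(seq_along(sel) %% 2 == 0,
                            bad$direction[sel], opp[sel])
  trials <- rbind(good[good$subject_id == 1, ], bad)
  pp <- preprocess(trials)
  expect_true(2 %in% pp$report$excluded_subjects)
  expect_false(2 %in% pp$trials$subject_id)
  expect_true(1 %in% pp$trials$subject_id)
})

test_that("preprocess is idempotent and drops control trials", {
  ch <- generate_cohort(cohort_spec(n_subjects = 3, seed = 4))
  p1 <- preprocess(ch$trials)
  expect_false("CONTROL" %in% p1$trials$condition)
  p2 <- preprocess(p1$trials)
  expect_identical(p1$trials, p2$trials)
  expect_equal(p2$report$removed_fraction, 0)
  expect_error(preprocess(transform(ch$trials, condition = "WAT")))
})

test_that("condition summaries reduce to the data they summarise", {
  ch <- generate_cohort(cohort_spec(n_subjects = 3, seed = 6))
  trials <- preprocess(ch$trials)$trials
  cs <- condition_summary(trials)
  expect_equal(nrow(cs), 12)
  # permutation invariance
  cs2 <- condition_summary(trials[sample.int(nrow(trials)), ])
  expect_equal(cs[order(cs$subject_id, cs$condition), ],
               cs2[order(cs2$subject_id, cs2$condition), ],
               ignore_attr = TRUE)
  # a single trial per cell is its own summary
  one <- trials[!duplicated(paste(trials$subject_id, trials$condition)), ]
  cs1 <- condition_summary(one)
  expect_equal(cs1$mean_rt, one$rt[order(one$subject_id, one$condition)])
  expect_equal(cs1$accuracy,
               as.numeric(one$choice == one$direction)[
                 order(one$subject_id, one$condition)])
})

test_that("lower generating drift yields lower summarised accuracy", {
  ch <- generate_cohort(cohort_spec(
    n_subjects = 12, seed = 8,
    mean_v = c(CON = 0.6, CON_BSL = 1.2, INC = 0.8, INC_BSL = 0.8),
    mean_a = 1.5, mean_ter = 0.35
  ))
  cs <- condition_summary(preprocess(ch$trials)$trials)
  acc <- tapply(cs$accuracy, cs$condition, mean)
  expect_lt(acc["CON"], acc["CON_BSL"])
})

test_that("mixed ANOVA is location-invariant in RT and returns the full table", {
  trials <- two_group_cohort(8, seed = 31)
  cs <- condition_summary(preprocess(trials)$trials)
  a1 <- mixed_anova(cs, "rt")
  expect_setequal(a1$effect,
                  c("group", "coherence", "group:coherence", "source",
                    "group:source", "coherence:source",
                    "group:coherence:source"))
  cs2 <- cs
  cs2$mean_rt <- cs2$mean_rt + 0.75
  a2 <- mixed_anova(cs2, "rt")
  expect_equal(a1$F, a2$F)
  expect_equal(a1$p, a2$p)
  # within-subject dfs follow the design
  expect_equal(a1$df2[a1$effect == "source"], 14)
})

test_that("ANOVA type-I error is calibrated on null cohorts", {
  set.seed(99)
  n_rep <- 400
  effects <- c("coherence", "source", "coherence:source")
  rej <- matrix(NA, n_rep, length(effects),
                dimnames = list(NULL, effects))
  for (r in seq_len(n_rep)) {
    cs <- expand.grid(subject_id = 1:16,
                      condition = c("CON", "CON_BSL", "INC", "INC_BSL"),
                      stringsAsFactors = FALSE)
    cs$group_angle <- ifelse(cs$subject_id <= 8, 20, 45)
    cs$accuracy <- rnorm(nrow(cs))
    cs$mean_rt <- 1
    a <- mixed_anova(cs, "accuracy")
    rej[r, ] <- a$p[match(effects, a$effect)] < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.08))
})

test_that("a true source effect is detected at experiment scale", {
  # lower drift whenever information is split across two sources
  hits <- vapply(1:8, function(r) {
    trials <- two_group_cohort(
      24, seed = 100 + 10 * r,
      mean_v = c(CON = 0.75, CON_BSL = 1.05, INC = 0.75, INC_BSL = 1.05),
      mean_a = 1.5, mean_ter = 0.35
    )
    cs <- condition_summary(preprocess(trials)$trials)
    a <- mixed_anova(cs, "accuracy")
    a$p[a$effect == "source"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 7 / 8)
})

test_that("paired contrasts handle identical and degenerate inputs", {
  cs <- expand.grid(subject_id = 1:10,
                    condition = c("CON", "CON_BSL", "INC", "INC_BSL"),
                    stringsAsFactors = FALSE)
  cs$group_angle <- 20
  set.seed(5)
  cs$accuracy <- rep(runif(10, 0.6, 0.9), 4)
  cs$mean_rt <- 1
  r <- paired_contrast(cs, "CON", "CON_BSL", "accuracy")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_false(r$degenerate)
  cs$accuracy[cs$condition == "CON"] <- cs$accuracy[cs$condition == "CON"] + 0.05
  r2 <- paired_contrast(cs, "CON", "CON_BSL", "accuracy")
  expect_true(r2$degenerate)
  expect_equal(r2$t, Inf)
  expect_equal(r2$mean_diff, 0.05)
  expect_error(paired_contrast(cs[cs$subject_id == 1, ], "CON", "CON_BSL",
                               "accuracy"))
})

test_that("noncentral-t power matches its identities", {
  expect_gte(power_paired_t(44, 0.5, 0.05), 0.90)
  # null identity: power at d = 0 is exactly alpha
  expect_equal(power_paired_t(30, 0, 0.05), 0.05, tolerance = 1e-12)
  # strictly increasing in n at fixed d > 0
  pw <- power_paired_t(seq(10, 100, by = 10), 0.5)
  expect_true(all(diff(pw) > 0))
  expect_error(power_paired_t(1, 0.5))
  expect_error(power_paired_t(44, 0.5, alpha = 1.5))
})
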