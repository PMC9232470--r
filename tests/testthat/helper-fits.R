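# Lazily computed, session-cached fixtures shared across test files, so the
# expensive hierarchical fits are run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# experiment-scale cohort with all three parameters varying by condition
recovery_cohort <- function() cached_fixture("recovery_cohort", {
  generate_cohort(cohort_spec(
    n_subjects = 45, seed = 11,
    mean_v = c(CON = 0.85, CON_BSL = 1.06, INC = 0.80, INC_BSL = 0.80),
    mean_a = c(CON = 1.5, CON_BSL = 1.5, INC = 1.3, INC_BSL = 1.5),
    mean_ter = 0.35
  ))
})

recovery_fit <- function() cached_fixture("recovery_fit", {
  trials <- preprocess(recovery_cohort()$trials)$trials
  hddm(trials, variant = c("v", "a", "ter"),
       n_samples = 4000, n_burn = 1000, n_chains = 3, seed = 5)
})

# small cohort for cheap unit tests of the fitting machinery
small_cohort <- function() cached_fixture("small_cohort", {
  generate_cohort(cohort_spec(n_subjects = 4, seed = 21))
})

small_fit <- function() cached_fixture("small_fit", {
  trials <- preprocess(small_cohort()$trials)$trials
  hddm(trials, variant = c("v", "a"),
       n_samples = 600, n_burn = 250, n_chains = 2, seed = 3)
})

# two-group cohort builder for the mixed-design statistics
two_group_cohort <- function(n_per_group, seed, ...) {
  a <- generate_cohort(cohort_spec(n_subjects = n_per_group,
                                   group_angle = 20, seed = seed, ...))
  b <- generate_cohort(cohort_spec(n_subjects = n_per_group,
                                   group_angle = 45, seed = seed + 1, ...))
  b$trials$subject_id <- b$trials$subject_id + n_per_group
  rbind(a$trials, b$trials)
}
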