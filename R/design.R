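# Synthetic behavioural data with the experiment's design structure:
# two groups (aperture angles +/-20 or +/-45 deg), 6 blocks x 72 trials
# (16 trials of each of four task conditions plus 8 control trials per
# block), signed coherences per condition, and DDM-governed responses.
#
# Direction coding: positive signed coherence drives leftward motion; for
# rightward trials both signs are flipped.  The generative DDM sees only the
# condition's net evidence, so drift is constant within a condition.

condition_coherences <- function(c_low, c_high) {
  # leftward-coded magnitudes (c1 dominant, |c1| >= |c2|)
  con <- sort(c(c_low, c_high - c_low), decreasing = TRUE)
  list(
    CON      = c(c1 = con[1], c2 = con[2]),
    CON_BSL  = c(c1 = c_high, c2 = 0),
    INC      = c(c1 = c_high, c2 = -(c_high - c_low)),
    INC_BSL  = c(c1 = c_low,  c2 = 0),
    CONTROL  = c(c1 = 0.60,   c2 = 0)
  )
}

#' Generate the trial design of the double-source motion experiment
#'
#' Builds the full 432-trial design (6 blocks of 72 trials: 16 trials of each
#' of the four task conditions plus 8 easy control trials per block, half
#' leftward and half rightward within every condition and block, order
#' randomised within block).  Signed coherences follow the factorial design:
#' congruent trials split the high combined coherence `c_high` into same-sign
#' `c_low` and `c_high - c_low`; incongruent trials oppose `c_high` and
#' `-(c_high - c_low)` for a net of `c_low`; baselines place all coherence in
#' one aperture; control trials use 60% and 0%.
#'
#' @param group_angle Aperture angle of the group, 20 or 45 degrees.
#' @param c_low,c_high Low and high combined coherence (fractions,
#'   `0 < c_low < c_high < 1`).
#' @param seed Optional integer seed controlling trial order.
#' @return A data frame of trial stubs with columns `subject_id` (NA),
#'   `group_angle`, `block`, `trial`, `condition`, `c1`, `c2`, `direction`,
#'   `choice` (`NA`), `rt` (`NA`), `is_valid` (`NA`).
#' @examples
#' d <- generate_design(20, 0.15, 0.20, seed = 1)
#' table(d$block, d$condition)
#' @export
generate_design <- function(group_angle = 20, c_low = 0.15, c_high = 0.20,
                            seed = NULL) {
  if (!group_angle %in% c(20, 45)) stop("'group_angle' must be 20 or 45")
  if (!(c_low > 0 && c_high < 1 && c_low < c_high))
    stop("need 0 < c_low < c_high < 1")
  if (!is.null(seed)) set.seed(seed)
  coh <- condition_coherences(c_low, c_high)
  n_per <- c(CON = 16L, CON_BSL = 16L, INC = 16L, INC_BSL = 16L, CONTROL = 8L)

  blocks <- lapply(1:6, function(b) {
    cond <- rep(names(n_per), n_per)
    dir <- unlist(lapply(n_per, function(k) rep(c("left", "right"), each = k / 2)),
                  use.names = FALSE)
    ord <- sample.int(length(cond))
    cond <- cond[ord]; dir <- dir[ord]
    sgn <- ifelse(dir == "left", 1, -1)
    m <- do.call(rbind, coh[cond])
    data.frame(
      subject_id = NA_integer_, group_angle = group_angle, block = b,
      trial = seq_along(cond),
      condition = cond,
      c1 = sgn * m[, "c1"], c2 = sgn * m[, "c2"],
      direction = dir, choice = NA_character_, rt = NA_real_,
      is_valid = NA, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Fill a design with DDM-generated responses
#'
#' Simulates a response for every trial of a design using condition-specific
#' drift-diffusion parameters.  The generative model is accuracy-coded: on
#' each trial the diffusion runs with the condition's drift towards the
#' correct boundary, and an upper absorption yields `choice == direction`.
#' Control trials get a drift mapped from their 60% coherence through the
#' same linear coherence-to-drift map used for task conditions
#' (`v = drift_scale * net coherence`), with boundary and non-decision time
#' averaged over the task conditions.  Trials that do not absorb before
#' `t_max` get `choice = "none"`, `rt = NA` and `is_valid = FALSE`.
#'
#' @param design A design from [generate_design()].
#' @param params Data frame with columns `condition`, `v`, `a`, `ter`, one
#'   row per task condition (CON, CON_BSL, INC, INC_BSL).
#' @param drift_scale Linear coherence-to-drift slope used for control
#'   trials.
#' @param t_max Response deadline in seconds.
#' @param dt Euler step for the trial simulator.
#' @param seed Optional integer seed.
#' @return The design with `choice`, `rt`, `is_valid` filled in.
#' @export
sample_behavior <- function(design, params, drift_scale = 5.3, t_max = 4,
                            dt = 0.001, seed = NULL) {
  stopifnot(all(c("condition", "v", "a", "ter") %in% names(params)))
  if (any(params$a <= 0)) stop("'a' must be positive for all conditions")
  if (any(params$ter < 0)) stop("'ter' must be non-negative")
  miss <- setdiff(.task_conditions, params$condition)
  if (length(miss)) stop("missing parameters for condition(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  ctrl <- data.frame(condition = "CONTROL",
                     v = drift_scale * 0.60,
                     a = mean(params$a), ter = mean(params$ter))
  par_all <- rbind(params[, c("condition", "v", "a", "ter")], ctrl)

  design$choice <- NA_character_
  design$rt <- NA_real_
  for (cd in unique(design$condition)) {
    idx <- which(design$condition == cd)
    pr <- par_all[par_all$condition == cd, ]
    sim <- simulate_ddm(length(idx), pr$v, pr$a, pr$ter, dt = dt, t_max = t_max)
    corr <- sim$boundary == "upper"
    opp <- ifelse(design$direction[idx] == "left", "right", "left")
    design$choice[idx] <- ifelse(sim$boundary == "none", "none",
                                 ifelse(corr, design$direction[idx], opp))
    design$rt[idx] <- sim$rt
  }
  design$is_valid <- design$choice != "none"
  design
}

#' Specify a synthetic cohort
#'
#' Describes the group-level generative distribution of a simulated cohort:
#' per-condition group means and SDs of the three DDM parameters, the design
#' coherences, and the outlier fraction of the generative mixture.  Defaults
#' emulate the qualitative pattern seen in double-source motion experiments:
#' a lower drift rate in the congruent double-source condition than its
#' baseline, and a lower boundary in the incongruent double-source condition.
#'
#' @param n_subjects Number of subjects (at least 2; group SDs are
#'   unidentifiable below that).
#' @param group_angle 20 or 45 degrees.
#' @param c_low,c_high Combined coherence levels.
#' @param mean_v,mean_a,mean_ter Group means, either scalars or length-4
#'   vectors ordered CON, CON_BSL, INC, INC_BSL.
#' @param sd_v,sd_a,sd_ter Group SDs (positive), scalars or length-4.
#' @param drift_scale Coherence-to-drift slope for control trials.
#' @param outlier_frac Fraction of trials replaced by uniform-outlier
#'   responses (random choice, RT uniform on `[0, t_max]`), mirroring the
#'   mixture assumed by the fitted model.
#' @param t_max Response deadline (seconds).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 45, group_angle = 20,
                        c_low = 0.15, c_high = 0.20,
                        mean_v = c(CON = 0.85, CON_BSL = 1.06,
                                   INC = 0.80, INC_BSL = 0.80),
                        mean_a = c(CON = 1.5, CON_BSL = 1.5,
                                   INC = 1.3, INC_BSL = 1.5),
                        mean_ter = 0.35,
                        sd_v = 0.3, sd_a = 0.15, sd_ter = 0.05,
                        drift_scale = 5.3, outlier_frac = 0.05,
                        t_max = 4, seed = 1L) {
  if (n_subjects < 2) stop("'n_subjects' must be at least 2")
  if (!(c_low > 0 && c_high < 1 && c_low < c_high))
    stop("need 0 < c_low < c_high < 1")
  as4 <- function(x, nm) {
    x <- rep_len(unname(x), 4)
    if (any(!is.finite(x))) stop("non-finite ", nm)
    setNames(x, .task_conditions)
  }
  spec <- list(
    n_subjects = as.integer(n_subjects), group_angle = group_angle,
    c_low = c_low, c_high = c_high,
    mean_v = as4(mean_v, "mean_v"), mean_a = as4(mean_a, "mean_a"),
    mean_ter = as4(mean_ter, "mean_ter"),
    sd_v = as4(sd_v, "sd_v"), sd_a = as4(sd_a, "sd_a"),
    sd_ter = as4(sd_ter, "sd_ter"),
    drift_scale = drift_scale, outlier_frac = outlier_frac,
    t_max = t_max, seed = as.integer(seed)
  )
  if (any(c(spec$sd_v, spec$sd_a, spec$sd_ter) <= 0))
    stop("group SDs must be positive")
  if (outlier_frac < 0 || outlier_frac >= 1)
    stop("'outlier_frac' must be in [0, 1)")
  structure(spec, class = "cohort_spec")
}

#' Read a cohort specification from a YAML file
#'
#' @param path Path to a YAML file whose fields match the arguments of
#'   [cohort_spec()].
#' @return A `cohort_spec` object.
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("mean_v", "mean_a", "mean_ter", "sd_v", "sd_a", "sd_ter"))
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  do.call(cohort_spec, x)
}

#' Generate a synthetic cohort of subjects
#'
#' The hierarchical generative twin of the fitted model: subject-level DDM
#' parameters are drawn from the condition-specific group normals of the
#' spec (redrawn until `a > 0.1` and `ter > 0.05`), each subject's 432-trial
#' design is built and filled with DDM responses, and a fraction
#' `outlier_frac` of responded trials is replaced by uniform outliers
#' (random choice, RT uniform on `[0, t_max]`).  Ground-truth group and
#' subject parameters are returned alongside for recovery studies.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `ddm_cohort`: a list with `trials` (the pooled
#'   trial table), `truth` (list with `group` means/SDs and `subjects`, the
#'   per-subject generating parameters) and `spec`.
#' @examples
#' ch <- generate_cohort(cohort_spec(n_subjects = 3, seed = 7))
#' nrow(ch$trials)  # 3 * 432
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  draw_trunc <- function(m, s, lo) {
    x <- rnorm(1, m, s)
    while (x <= lo) x <- rnorm(1, m, s)
    x
  }
  subj_par <- vector("list", spec$n_subjects)
  trials <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    pr <- data.frame(
      condition = .task_conditions,
      v = rnorm(4, spec$mean_v, spec$sd_v),
      a = vapply(.task_conditions, function(cd)
        draw_trunc(spec$mean_a[cd], spec$sd_a[cd], 0.1), 0),
      ter = vapply(.task_conditions, function(cd)
        draw_trunc(spec$mean_ter[cd], spec$sd_ter[cd], 0.05), 0),
      stringsAsFactors = FALSE, row.names = NULL
    )
    d <- generate_design(spec$group_angle, spec$c_low, spec$c_high)
    d <- sample_behavior(d, pr, drift_scale = spec$drift_scale,
                         t_max = spec$t_max)
    d$subject_id <- i
    # generative outlier mixture (matches the fitted 95/5 mixture model)
    if (spec$outlier_frac > 0) {
      is_out <- runif(nrow(d)) < spec$outlier_frac
      if (any(is_out)) {
        d$choice[is_out] <- sample(c("left", "right"), sum(is_out),
                                   replace = TRUE)
        d$rt[is_out] <- runif(sum(is_out), 0, spec$t_max)
        d$is_valid[is_out] <- TRUE
      }
    }
    subj_par[[i]] <- pr
    trials[[i]] <- d
  }
  structure(list(
    trials = do.call(rbind, trials),
    truth = list(
      group = list(mean_v = spec$mean_v, mean_a = spec$mean_a,
                   mean_ter = spec$mean_ter, sd_v = spec$sd_v,
                   sd_a = spec$sd_a, sd_ter = spec$sd_ter),
      subjects = subj_par
    ),
    spec = spec
  ), class = "ddm_cohort")
}

#' @export
print.ddm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d trials (group angle %d deg, c_low = %.3g, c_high = %.3g)\n",
              x$spec$n_subjects, nrow(x$trials) / x$spec$n_subjects,
              x$spec$group_angle, x$spec$c_low, x$spec$c_high))
  invisible(x)
}

#' Write / read a trial table as CSV
#'
#' Plain-CSV persistence of trial tables with the canonical column set;
#' RTs are written in seconds with six decimal places.
#'
#' @param trials A trial data frame.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns the
#'   trial data frame.
#' @export
write_trials <- function(trials, path) {
  out <- trials[, c("subject_id", "group_angle", "block", "trial", "condition",
                    "c1", "c2", "direction", "choice", "rt", "is_valid")]
  out$rt <- ifelse(is.na(out$rt), "", sprintf("%.6f", out$rt))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$rt <- suppressWarnings(as.numeric(x$rt))
  x$is_valid <- as.logical(x$is_valid)
  bad <- setdiff(unique(x$condition), .all_conditions)
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  x
}
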