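# Behavioural preprocessing and statistics: exclusion filters, per-subject
# condition summaries, the 2x2 repeated-measures ANOVA with a between-group
# factor, paired contrasts, and the exact noncentral-t power of the paired
# t-test.

#' Preprocess a trial table
#'
#' Applies the study's exclusion rules: trials with RT faster than 250 ms
#' (fast guesses) and trials without a valid response are removed; subjects
#' whose accuracy over any pair of consecutive blocks (1-2, 3-4, 5-6,
#' computed over all responded trials including control) falls below 60% are
#' excluded entirely; control trials are then dropped from the analysis set.
#' The filter is idempotent.
#'
#' @param trials A trial data frame (see [generate_design()] for the schema).
#' @param rt_min Fast-guess cutoff in seconds.
#' @param min_accuracy Block-pair accuracy threshold for subject exclusion.
#' @return A list with `trials` (the filtered analysis set) and `report`:
#'   `n_total`, `n_fast`, `n_no_response`, `removed_fraction`
#'   (fast + no-response over all input trials), `excluded_subjects` and
#'   `n_control_dropped`.
#' @examples
#' ch <- generate_cohort(cohort_spec(n_subjects = 2, seed = 1))
#' pp <- preprocess(ch$trials)
#' pp$report$removed_fraction
#' @export
preprocess <- function(trials, rt_min = 0.250, min_accuracy = 0.60) {
  bad <- setdiff(unique(trials$condition), .all_conditions)
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  n_total <- nrow(trials)
  no_resp <- trials$choice == "none" | is.na(trials$rt)
  fast <- !no_resp & trials$rt < rt_min
  keep <- trials[!(no_resp | fast), , drop = FALSE]

  # block-pair accuracy check on responded trials (control included)
  excluded <- integer(0)
  for (sid in unique(keep$subject_id)) {
    s <- keep[keep$subject_id == sid, ]
    for (b in c(1, 3, 5)) {
      pair <- s[s$block %in% c(b, b + 1), ]
      if (nrow(pair) > 0 &&
          mean(pair$choice == pair$direction) < min_accuracy) {
        excluded <- c(excluded, sid)
        break
      }
    }
  }
  keep <- keep[!keep$subject_id %in% excluded, , drop = FALSE]
  n_control <- sum(keep$condition == "CONTROL")
  keep <- keep[keep$condition != "CONTROL", , drop = FALSE]
  rownames(keep) <- NULL
  list(
    trials = keep,
    report = list(
      n_total = n_total,
      n_fast = sum(fast),
      n_no_response = sum(no_resp),
      removed_fraction = (sum(fast) + sum(no_resp)) / n_total,
      excluded_subjects = unique(excluded),
      n_control_dropped = n_control
    )
  )
}

#' Per-subject condition summaries
#'
#' Mean decision accuracy and mean RT per subject and task condition.
#' RT pools correct and error trials by default (set
#' `correct_only = TRUE` for correct trials only).
#'
#' @param trials A preprocessed trial table (task conditions only).
#' @param correct_only Restrict the RT mean to correct trials?
#' @return A data frame with `subject_id`, `group_angle`, `condition`,
#'   `accuracy`, `mean_rt`, `n_trials`.  Empty cells yield `NaN` with a
#'   warning.
#' @export
condition_summary <- function(trials, correct_only = FALSE) {
  trials <- trials[trials$condition %in% .task_conditions, , drop = FALSE]
  grid <- expand.grid(subject_id = unique(trials$subject_id),
                      condition = .task_conditions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    s <- trials[trials$subject_id == grid$subject_id[k] &
                trials$condition == grid$condition[k], ]
    corr <- s$choice == s$direction
    rt <- if (correct_only) s$rt[corr] else s$rt
    data.frame(
      subject_id = grid$subject_id[k],
      group_angle = if (nrow(s)) s$group_angle[1] else NA_real_,
      condition = grid$condition[k],
      accuracy = mean(corr),
      mean_rt = mean(rt),
      n_trials = nrow(s), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (any(out$n_trials == 0))
    warning("empty subject x condition cells; summaries are NaN")
  out[order(out$subject_id, out$condition), ]
}

#' Mixed 2x2 repeated-measures ANOVA
#'
#' The group-inference model of the study: a 2 (coherence level: high for
#' CON/CON_BSL, low for INC/INC_BSL) x 2 (information sources: double for
#' CON/INC, single for the baselines) within-subject design with aperture
#' group as a between-subject factor, fitted with classical sums of squares
#' via `stats::aov` with an `Error(subject/(coherence*source))` stratum
#' structure.  Subjects with missing cells are dropped with a warning.
#'
#' @param summary A [condition_summary()] table.
#' @param dependent `"accuracy"` or `"rt"`.
#' @return A data frame with one row per effect (`group`, `coherence`,
#'   `group:coherence`, `source`, `group:source`, `coherence:source`,
#'   `group:coherence:source`): `F`, `df1`, `df2`, `p`, `peta2` (partial
#'   eta squared, effect SS over effect SS plus its stratum residual SS).
#' @export
mixed_anova <- function(summary, dependent = c("accuracy", "rt")) {
  dependent <- match.arg(dependent)
  d <- summary
  d$y <- if (dependent == "accuracy") d$accuracy else d$mean_rt
  cells <- tapply(is.finite(d$y), d$subject_id, sum)
  incomplete <- names(cells)[cells < 4]
  if (length(incomplete)) {
    warning("dropping subject(s) with missing cells: ",
            paste(incomplete, collapse = ", "))
    d <- d[!d$subject_id %in% incomplete, ]
  }
  if (length(unique(d$subject_id)) < 3) stop("too few complete subjects")
  d$subject <- factor(d$subject_id)
  d$group <- factor(d$group_angle)
  d$coherence <- factor(ifelse(d$condition %in% c("CON", "CON_BSL"),
                               "high", "low"))
  d$source <- factor(ifelse(d$condition %in% c("CON", "INC"),
                            "double", "single"))
  one_group <- nlevels(d$group) < 2
  form <- if (one_group)
    y ~ coherence * source + Error(subject / (coherence * source))
  else
    y ~ group * coherence * source + Error(subject / (coherence * source))
  fit <- aov(form, data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    res_ss <- tab[eff == "Residuals", "Sum Sq"]
    res_df <- tab[eff == "Residuals", "Df"]
    for (j in which(eff != "Residuals")) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff[j],
        F = tab[j, "F value"], df1 = tab[j, "Df"], df2 = res_df,
        p = tab[j, "Pr(>F)"],
        peta2 = tab[j, "Sum Sq"] / (tab[j, "Sum Sq"] + res_ss),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired contrast between two conditions
#'
#' Classical paired t-test on per-subject summaries of two conditions.
#' Identical columns give `t = 0`, `p = 1`; a constant non-zero difference
#' (zero variance) is reported as degenerate with an infinite t.
#'
#' @param summary A [condition_summary()] table.
#' @param condA,condB Condition labels to contrast (A minus B).
#' @param dependent `"accuracy"` or `"rt"`.
#' @return A list with `mean_diff`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_contrast <- function(summary, condA, condB,
                            dependent = c("accuracy", "rt")) {
  dependent <- match.arg(dependent)
  col <- if (dependent == "accuracy") "accuracy" else "mean_rt"
  a <- summary[summary$condition == condA, c("subject_id", col)]
  b <- summary[summary$condition == condB, c("subject_id", col)]
  m <- merge(a, b, by = "subject_id", suffixes = c(".a", ".b"))
  m <- m[is.finite(m[[2]]) & is.finite(m[[3]]), ]
  if (nrow(m) < 2) stop("need at least 2 subjects with both conditions")
  diffs <- m[[2]] - m[[3]]
  n <- length(diffs)
  if (sd(diffs) == 0) {
    if (mean(diffs) == 0)
      return(list(mean_diff = 0, t = 0, df = n - 1, p = 1, degenerate = FALSE))
    return(list(mean_diff = mean(diffs), t = sign(mean(diffs)) * Inf,
                df = n - 1, p = 0, degenerate = TRUE))
  }
  tt <- t.test(diffs)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}

#' Exact power of the paired t-test
#'
#' Power of a two-sided one-sample/paired t-test at effect size `d`
#' (Cohen's d on the paired differences) and sample size `n`, computed from
#' the noncentral t distribution with noncentrality `d * sqrt(n)` and
#' `n - 1` degrees of freedom.  At `d = 0` the power equals `alpha`.
#'
#' @param n Number of pairs (>= 2).
#' @param d Standardised effect size.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @examples
#' power_paired_t(44, 0.5)   # > 0.90
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  if (any(n < 2)) stop("'n' must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  df <- n - 1
  ncp <- d * sqrt(n)
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp) + 1 - pt(tcrit, df, ncp)
}
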