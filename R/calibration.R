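#' Monte-Carlo calibration / power study over simulated cohorts
#'
#' Draws many independent cohorts under one scenario and runs the full
#' statistical chain on each — behavior-sorted split-half correlations per
#' subject ([split_half_correlations]), then the three 1-df
#' within-subject effects and the two post-hoc tests
#' ([rm_anova_1df], [paired_t]) — returning the per-cohort p values and
#' verdicts.  Under \code{scenario = "null"} the rejection rates estimate
#' the type-I error of each test; under the effect scenarios they estimate
#' power.
#'
#' Cohorts are simulated at the trial-amplitude level: true amplitudes
#' follow the ground-truth stability model and estimation noise of SD
#' \code{beta_noise_sd} stands in for the BOLD encode/estimate round trip,
#' whose fidelity is established separately by the noiseless-recovery
#' property.  Trial order within a run is irrelevant to the split-half
#' statistic, so no temporal layout is drawn.
#'
#' @param n_cohorts number of cohorts.
#' @param scenario representational scenario (see [make_ground_truth]).
#' @param master_seed integer seed; cohort c, subject i uses a child seed.
#' @param n_subjects subjects per cohort (default 13).
#' @param n_runs runs per subject (default 4: a reduced session).
#' @param n_voxels ROI size in voxels (default 28).
#' @param n_veridical,n_scrambled trials per condition per run.
#' @param p_correct per-condition P(correct), as in [behavior_params].
#' @param p_no_response no-response rate.
#' @param stability_base,stability_effect,pattern_mean,pattern_sd,trial_noise_sd
#'   ground-truth knobs, as in [make_ground_truth].
#' @param beta_noise_sd estimation-noise SD per trial beta.
#' @param match_counts run the matched-trial control instead of the plain
#'   analysis.
#' @param alpha significance level for verdicts.
#' @return data frame, one row per cohort: p values of the condition,
#'   response and interaction effects and both post-hocs, the group-mean
#'   correlation of each cell, and the verdict.
#' @export
calibration_study <- function(n_cohorts, scenario = "null", master_seed = 1L,
                              n_subjects = 13, n_runs = 4, n_voxels = 28,
                              n_veridical = 36, n_scrambled = 36,
                              p_correct = c(veridical = 0.847,
                                            scrambled = 0.727),
                              p_no_response = 0.001,
                              stability_base = 0, stability_effect = 0.7,
                              pattern_mean = c(veridical = 1,
                                               scrambled = 0.93),
                              pattern_sd = 1, trial_noise_sd = 1,
                              beta_noise_sd = 4.2, match_counts = FALSE,
                              alpha = 0.05) {
  stab <- stability_table(if (scenario == "null") "null" else scenario,
                          stability_base, stability_effect)
  conds <- rep(c(rep("veridical", n_veridical), rep("scrambled", n_scrambled)),
               n_runs)
  runs <- rep(seq_len(n_runs), each = n_veridical + n_scrambled)
  n_tr <- length(conds)
  pc <- p_correct[conds]
  cond_mean <- pattern_mean[c("veridical", "veridical", "scrambled",
                              "scrambled")]

  one_subject <- function(seed) {
    with_seed(seed, {
      responded <- stats::runif(n_tr) >= p_no_response
      resp <- ifelse(!responded, "none",
                     ifelse(stats::runif(n_tr) < pc, "correct", "incorrect"))
      cellf <- paste(conds, ifelse(resp == "none", "correct", resp),
                     sep = ".")
      P <- matrix(stats::rnorm(n_voxels * 4, sd = pattern_sd), n_voxels, 4,
                  dimnames = list(NULL, cell_names))
      P <- sweep(P, 2, cond_mean, `+`)
      s <- stab[cellf]
      eps <- matrix(stats::rnorm(n_voxels * n_tr, sd = trial_noise_sd),
                    n_voxels, n_tr)
      amp <- sweep(P[, cellf, drop = FALSE], 2, s, `*`) +
        sweep(eps, 2, 1 - s, `*`) +
        matrix(stats::rnorm(n_voxels * n_tr, sd = beta_noise_sd),
               n_voxels, n_tr)
    })
    meta <- data.frame(trial_id = seq_len(n_tr), run_id = runs,
                       condition = conds, response = resp,
                       stringsAsFactors = FALSE)
    te <- new_trial_estimates(amp, meta)
    te <- suppressMessages(filter_trials(te))
    if (match_counts) {
      te <- suppressWarnings(match_trial_counts(te, seed))
    }
    split_half_correlations(te, seq_len(n_voxels))
  }

  out <- vector("list", n_cohorts)
  cw <- contrasts_2x2()
  for (ch in seq_len(n_cohorts)) {
    tab <- t(vapply(seq_len(n_subjects), function(i) {
      sh <- one_subject(child_seed(master_seed, "cohort", ch, i))
      stats::setNames(sh$r, paste(sh$condition, sh$response,
                                  sep = "."))[cell_names]
    }, numeric(4)))
    colnames(tab) <- cell_names
    inf <- roi_inference_2x2(tab)
    eff <- inf$effects; ph <- inf$posthoc
    out[[ch]] <- data.frame(
      cohort = ch,
      p_condition = eff$condition$p, p_response = eff$response$p,
      p_interaction = eff$interaction$p,
      p_posthoc_veridical = ph$veridical$p,
      p_posthoc_scrambled = ph$scrambled$p,
      diff_veridical = ph$veridical$mean_diff,
      diff_scrambled = ph$scrambled$mean_diff,
      r_veridical_correct = mean(tab[, "veridical.correct"], na.rm = TRUE),
      r_veridical_incorrect = mean(tab[, "veridical.incorrect"], na.rm = TRUE),
      r_scrambled_correct = mean(tab[, "scrambled.correct"], na.rm = TRUE),
      r_scrambled_incorrect = mean(tab[, "scrambled.incorrect"], na.rm = TRUE),
      verdict = scenario_verdict(inf, alpha),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "scenario") <- scenario
  attr(res, "alpha") <- alpha
  res
}

#' Rejection rates of each test in a calibration study
#'
#' @param study output of [calibration_study].
#' @param alpha significance level (defaults to the study's).
#' @return named vector of rejection rates over cohorts.
#' @export
rejection_rates <- function(study, alpha = attr(study, "alpha")) {
  pcols <- c(condition = "p_condition", response = "p_response",
             interaction = "p_interaction",
             posthoc_veridical = "p_posthoc_veridical",
             posthoc_scrambled = "p_posthoc_scrambled")
  vapply(pcols, function(cl) mean(study[[cl]] < alpha, na.rm = TRUE), 0)
}
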