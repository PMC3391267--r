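#' Simulate one subject's session and estimate trial amplitudes
#'
#' Two simulation levels are offered:
#' \describe{
#'   \item{bold}{the full route: event-related designs, behavioral draws,
#'     BOLD time series with AR(1) noise and drift, and least-squares-all
#'     trial-beta estimation restricted to the ROI voxels.}
#'   \item{amplitude}{the amplitude-level shortcut: the same behavioral
#'     draws and the same stability model for true trial amplitudes, with
#'     the BOLD encode/estimate round trip replaced by additive Gaussian
#'     estimation noise of SD \code{beta_noise_sd} per trial beta.  The
#'     noiseless-recovery property (trial-beta estimation inverts the BOLD
#'     encoding exactly) justifies the shortcut; it is used for studies
#'     that draw thousands of cohorts.}
#' }
#' \code{beta_noise_sd}'s default matches the empirical trial-beta noise
#' of the bold route under the default [noise_model], so the two levels
#' are statistically exchangeable for the split-half analysis.
#'
#' @param subject_id subject label (part of the seed stream).
#' @param master_seed integer master seed for the cohort.
#' @param scenario representational scenario, see [make_ground_truth].
#' @param geometry a [geometry_params] list.
#' @param n_runs number of experimental runs (default 10).
#' @param level \code{"bold"} or \code{"amplitude"}.
#' @param design_p,behavior_p,noise,hrf_p module parameter blocks.
#' @param gt_args extra arguments passed to [make_ground_truth].
#' @param beta_noise_sd estimation-noise SD for the amplitude level.
#' @param keep_raw also return per-run designs, behaviors and (bold level)
#'   BOLD runs, for pipelines that write stage artifacts.
#' @param mask voxel indices to estimate over; defaults to the union of
#'   the ground truth's ROI voxels.
#' @return list: \code{trial_estimates} (all trials, labelled),
#'   \code{ground_truth}, \code{behavior} (all runs); with
#'   \code{keep_raw}, also \code{runs} (per-run design / behavior / bold).
#' @export
simulate_subject <- function(subject_id, master_seed, scenario = "holistic",
                             geometry = geometry_params(), n_runs = 10,
                             level = c("bold", "amplitude"),
                             design_p = design_params(),
                             behavior_p = behavior_params(),
                             noise = noise_model(), hrf_p = hrf_params(),
                             gt_args = list(), beta_noise_sd = 4.2,
                             keep_raw = FALSE, mask = NULL) {
  level <- match.arg(level)
  gt <- do.call(make_ground_truth,
                c(list(scenario = scenario, geometry = geometry,
                       seed = child_seed(master_seed, subject_id, "gt")),
                  gt_args))
  roi_vox <- if (is.null(mask)) {
    sort(unlist(gt$roi_masks[setdiff(names(gt$roi_masks), "background")]))
  } else sort(mask)
  sseed <- child_seed(master_seed, subject_id)

  if (level == "bold") {
    per_run <- lapply(seq_len(n_runs), function(r) {
      des <- generate_experimental_design(r, sseed, design_p)
      beh <- simulate_behavior(des, behavior_p, sseed)
      bold <- simulate_bold_run(des, beh, gt, noise, sseed, hrf_p)
      te <- estimate_trial_betas(bold, des, hrf_p, behavior = beh,
                                 mask = roi_vox)
      out <- list(te = te, beh = beh)
      if (keep_raw) {
        out$design <- des
        out$bold <- bold
      }
      out
    })
    te <- combine_trial_estimates(lapply(per_run, `[[`, "te"))
    behavior <- do.call(rbind, lapply(per_run, `[[`, "beh"))
  } else {
    per_run <- lapply(seq_len(n_runs), function(r) {
      des <- generate_experimental_design(r, sseed, design_p)
      beh <- simulate_behavior(des, behavior_p, sseed)
      amp <- true_roi_amplitudes(gt, beh, roi_vox,
                                 child_seed(sseed, "run", r, "amp"))
      est <- amp + with_seed(child_seed(sseed, "run", r, "estnoise"), {
        matrix(stats::rnorm(length(amp), sd = beta_noise_sd),
               nrow(amp), ncol(amp))
      })
      meta <- data.frame(trial_id = beh$trial_id, run_id = r,
                         condition = beh$condition, response = beh$response,
                         stringsAsFactors = FALSE)
      out <- list(te = new_trial_estimates(est, meta, voxel_indices = roi_vox),
                  beh = beh)
      if (keep_raw) out$design <- des
      out
    })
    te <- combine_trial_estimates(lapply(per_run, `[[`, "te"))
    behavior <- do.call(rbind, lapply(per_run, `[[`, "beh"))
  }
  res <- list(trial_estimates = te, ground_truth = gt, behavior = behavior,
              subject_id = subject_id)
  if (keep_raw) res$runs <- per_run
  res
}

# true amplitudes restricted to ROI voxels (rows ordered as roi_vox)
true_roi_amplitudes <- function(gt, behavior, roi_vox, seed) {
  n_tr <- nrow(behavior)
  cellf <- paste(behavior$condition,
                 ifelse(behavior$response == "none", "correct",
                        behavior$response), sep = ".")
  amp <- matrix(0, length(roi_vox), n_tr,
                dimnames = list(NULL, behavior$trial_id))
  with_seed(seed, {
    for (nm in setdiff(names(gt$roi_masks), "background")) {
      rows <- match(gt$roi_masks[[nm]], roi_vox)
      s <- gt$stability[nm, cellf]
      eps <- matrix(stats::rnorm(length(rows) * n_tr, sd = gt$trial_noise_sd),
                    length(rows), n_tr)
      amp[rows, ] <- sweep(gt$patterns[[nm]][, cellf, drop = FALSE], 2, s, `*`) +
        sweep(eps, 2, 1 - s, `*`)
    }
  })
  amp
}

#' Split-half analysis of one simulated subject
#'
#' Filters unresponded trials and computes the four behavior-sorted
#' split-half correlations (and the mean-magnitude table) for every ROI,
#' optionally after matched-trial subsampling.
#'
#' @param subject output of [simulate_subject].
#' @param match_counts apply [match_trial_counts] first (default FALSE).
#' @param match_seed seed for the matching subsample.
#' @return named list per ROI with \code{split_half} and
#'   \code{mean_magnitude} entries.
#' @export
analyze_subject <- function(subject, match_counts = FALSE, match_seed = 1L) {
  te <- suppressMessages(filter_trials(subject$trial_estimates))
  if (match_counts) te <- suppressWarnings(match_trial_counts(te, match_seed))
  gt <- subject$ground_truth
  rois <- setdiff(names(gt$roi_masks), "background")
  out <- lapply(rois, function(nm) {
    rows <- roi_rows(te, gt$roi_masks[[nm]])
    list(split_half = split_half_correlations(te, rows),
         mean_magnitude = roi_mean_magnitude(te, rows))
  })
  stats::setNames(out, rois)
}

#' Simulate and analyze a cohort of subjects
#'
#' @inheritParams simulate_subject
#' @param n_subjects cohort size (default 13).
#' @param match_counts also compute the matched-trial control analysis.
#' @return a \code{cohort_result}: per-subject analyses, per-ROI cell
#'   tables of split-half correlations (subjects x 4 cells), behavioral
#'   records per subject, scenario.
#' @export
simulate_cohort <- function(n_subjects = 13, scenario = "holistic",
                            master_seed = 1L,
                            geometry = geometry_params(), n_runs = 10,
                            level = c("bold", "amplitude"),
                            design_p = design_params(),
                            behavior_p = behavior_params(),
                            noise = noise_model(), hrf_p = hrf_params(),
                            gt_args = list(), beta_noise_sd = 4.2,
                            match_counts = FALSE) {
  level <- match.arg(level)
  subjects <- paste0("sub", sprintf("%02d", seq_len(n_subjects)))
  analyses <- list()
  matched <- list()
  behaviors <- list()
  for (subj in subjects) {
    s <- simulate_subject(subj, master_seed, scenario, geometry, n_runs,
                          level, design_p, behavior_p, noise, hrf_p,
                          gt_args, beta_noise_sd)
    analyses[[subj]] <- analyze_subject(s)
    if (match_counts) {
      analyses_m <- analyze_subject(s, match_counts = TRUE,
                                    match_seed = child_seed(master_seed, subj))
      matched[[subj]] <- analyses_m
    }
    behaviors[[subj]] <- s$behavior
  }
  rois <- names(analyses[[1]])
  structure(list(analyses = analyses, matched = matched,
                 behaviors = behaviors, rois = rois, scenario = scenario,
                 n_runs = n_runs, level = level, master_seed = master_seed),
            class = "cohort_result")
}

#' Subjects x cells table of split-half correlations for one ROI
#'
#' Rows are subjects, columns the four stimulus x response cells; cells
#' flagged undefined are \code{NA} (handled listwise downstream).
#'
#' @param cohort a \code{cohort_result} (or its \code{analyses} list).
#' @param roi ROI name.
#' @param matched use the matched-trial analyses instead.
#' @return numeric matrix subjects x 4 with cell names.
#' @export
cohort_cell_table <- function(cohort, roi, matched = FALSE) {
  analyses <- if (inherits(cohort, "cohort_result")) {
    if (matched) cohort$matched else cohort$analyses
  } else cohort
  tab <- t(vapply(analyses, function(a) {
    sh <- a[[roi]]$split_half
    key <- paste(sh$condition, sh$response, sep = ".")
    stats::setNames(sh$r, key)[cell_names]
  }, numeric(4)))
  colnames(tab) <- cell_names
  tab
}

#' Subjects x cells table of mean ROI magnitudes for one ROI
#' @inheritParams cohort_cell_table
#' @export
cohort_magnitude_table <- function(cohort, roi) {
  analyses <- if (inherits(cohort, "cohort_result")) cohort$analyses else cohort
  tab <- t(vapply(analyses, function(a) {
    mm <- a[[roi]]$mean_magnitude
    key <- paste(mm$condition, mm$response, sep = ".")
    stats::setNames(mm$mean_amplitude, key)[cell_names]
  }, numeric(4)))
  colnames(tab) <- cell_names
  tab
}
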