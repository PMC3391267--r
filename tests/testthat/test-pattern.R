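te_from <- function(amp, meta) patternsplit:::new_trial_estimates(amp, meta)

test_that("no-response trials are excluded, with degenerate cases handled", {
  inst <- random_instance(n_vox = 4, trials_per_cell_per_run = 3)
  m <- inst$meta
  m$response[5] <- "none"
  te <- te_from(inst$amp, m)
  expect_message(f <- filter_trials(te), "1 of 24")
  expect_equal(ncol(f$amplitudes), 23)
  expect_false("none" %in% f$meta$response)

  clean <- te_from(inst$amp, inst$meta)
  expect_identical(suppressMessages(filter_trials(clean)), clean)

  m$response <- "none"
  expect_error(filter_trials(te_from(inst$amp, m)), "all trials")
})

test_that("split-half correlations equal the brute-force oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    inst <- random_instance(n_vox = 5, trials_per_cell_per_run = 2,
                            n_runs = 2)
    te <- te_from(inst$amp, inst$meta)
    res <- split_half_correlations(te, seq_len(5))
    oracle <- split_half_oracle(inst$amp, inst$meta)
    got <- stats::setNames(res$r, paste(res$condition, res$response,
                                        sep = "."))
    expect_equal(got[CELLS], oracle[CELLS], tolerance = 1e-12)
  }
})

test_that("identical halves give r = 1 in every cell", {
  geom <- reduced_geometry()
  gt <- make_ground_truth("null", geom, seed = 1, stability_base = 1)
  sub <- simulate_subject("s", 1, "null", geom, n_runs = 2,
                          level = "amplitude", beta_noise_sd = 0,
                          gt_args = list(stability_base = 1))
  te <- suppressMessages(filter_trials(sub$trial_estimates))
  res <- split_half_correlations(te, seq_len(28))
  expect_true(all(res$flag == "ok"))
  expect_equal(res$r, rep(1, 4), tolerance = 1e-10)
})

test_that("centering removes any per-voxel offset shared by all cells", {
  set.seed(3)
  inst <- random_instance(n_vox = 6, trials_per_cell_per_run = 3)
  te <- te_from(inst$amp, inst$meta)
  base <- split_half_correlations(te, 1:6)
  offset_odd <- rnorm(6); offset_even <- rnorm(6)
  amp2 <- inst$amp
  odd_cols <- inst$meta$run_id %% 2 == 1
  amp2[, odd_cols] <- amp2[, odd_cols] + offset_odd
  amp2[, !odd_cols] <- amp2[, !odd_cols] + offset_even
  shifted <- split_half_correlations(te_from(amp2, inst$meta), 1:6)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
})

test_that("correlations are invariant to positive rescaling of one half", {
  set.seed(4)
  inst <- random_instance(n_vox = 6, trials_per_cell_per_run = 3)
  te <- te_from(inst$amp, inst$meta)
  base <- split_half_correlations(te, 1:6)
  amp2 <- inst$amp
  odd_cols <- inst$meta$run_id %% 2 == 1
  amp2[, odd_cols] <- amp2[, odd_cols] * 17.3
  scaled <- split_half_correlations(te_from(amp2, inst$meta), 1:6)
  expect_equal(scaled$r, base$r, tolerance = 1e-12)
})

test_that("undefined cells are flagged, not silently zeroed", {
  set.seed(5)
  inst <- random_instance(n_vox = 5, trials_per_cell_per_run = 2)
  m <- inst$meta
  # remove every veridical.incorrect trial from even runs
  drop <- m$condition == "veridical" & m$response == "incorrect" &
    m$run_id %% 2 == 0
  te <- te_from(inst$amp[, !drop], m[!drop, ])
  res <- split_half_correlations(te, 1:5)
  vi <- res[res$condition == "veridical" & res$response == "incorrect", ]
  expect_equal(vi$flag, "empty_cell")
  expect_true(is.na(vi$r))
  expect_equal(vi$n_even, 0L)
  # zero variance
  amp0 <- inst$amp; amp0[] <- 5
  res0 <- split_half_correlations(te_from(amp0, inst$meta), 1:5)
  expect_true(all(res0$flag == "zero_variance"))
})

test_that("matched-trial subsampling equalizes counts within response", {
  set.seed(6)
  n_v <- 30; n_s <- 22
  meta <- data.frame(
    trial_id = 1:((n_v + n_s) * 2),
    run_id = rep(1:2, each = n_v + n_s),
    condition = rep(c(rep("veridical", n_v), rep("scrambled", n_s)), 2),
    response = "correct", stringsAsFactors = FALSE)
  amp <- matrix(rnorm(3 * nrow(meta)), 3, nrow(meta))
  te <- te_from(amp, meta)
  m <- match_trial_counts(te, seed = 1)
  for (h in 1:2) {
    counts <- table(m$meta$condition[m$meta$run_id == h])
    expect_equal(unname(counts["veridical"]), unname(counts["scrambled"]))
    expect_equal(unname(counts["scrambled"]), n_s)
  }
  expect_identical(match_trial_counts(te, seed = 1)$meta,
                   m$meta)
  # already balanced: identity up to ordering
  bal <- te_from(amp[, meta$condition == "scrambled"],
                 meta[meta$condition == "scrambled", ])
  bal$meta$condition <- rep(c("veridical", "scrambled"), length.out = n_s * 2)
  mb <- match_trial_counts(bal, seed = 2)
  expect_equal(ncol(mb$amplitudes), ncol(bal$amplitudes))
})

test_that("mean magnitude is constant-faithful and linear", {
  inst <- random_instance(n_vox = 4, trials_per_cell_per_run = 2)
  te <- te_from(inst$amp, inst$meta)
  mm <- roi_mean_magnitude(te, 1:4)
  expect_equal(nrow(mm), 4)
  const <- te_from(inst$amp * 0 + 2.5, inst$meta)
  mmc <- roi_mean_magnitude(const, 1:4)
  expect_equal(mmc$mean_amplitude, rep(2.5, 4))
  doubled <- roi_mean_magnitude(te_from(inst$amp * 2, inst$meta), 1:4)
  expect_equal(doubled$mean_amplitude, 2 * mm$mean_amplitude)
})

test_that("group mean magnitudes recover the scrambled/veridical ratio", {
  # generator scales the scrambled mean amplitude to 0.93 of veridical;
  # a large ROI keeps the voxel-sampling noise of the ratio small
  geom <- geometry_params(dim = c(12L, 12L, 6L),
                          rois = list(ffa_like = list(center = c(6, 6, 3),
                                                      n_voxels = 500L)))
  ratios <- vapply(1:6, function(s) {
    sub <- simulate_subject(paste0("s", s), s, "null", geom, n_runs = 4,
                            level = "amplitude", beta_noise_sd = 1,
                            gt_args = list(stability_base = 0.5))
    mm <- roi_mean_magnitude(
      suppressMessages(filter_trials(sub$trial_estimates)), 1:500)
    mean(mm$mean_amplitude[mm$condition == "scrambled"]) /
      mean(mm$mean_amplitude[mm$condition == "veridical"])
  }, 0)
  expect_equal(mean(ratios), 0.93, tolerance = 0.05)
})
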