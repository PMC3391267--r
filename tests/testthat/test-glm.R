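make_fit_fixture <- function(seed = 1, n_vox = 7) {
  d <- generate_experimental_design(1, seed)
  dm <- build_design_matrix(d, mode = "trial", drift_order = 1)
  set.seed(seed)
  B <- matrix(rnorm(ncol(dm$X) * n_vox), ncol(dm$X), n_vox)
  list(design = d, dm = dm, B = B, Y = dm$X %*% B)
}

test_that("OLS recovers generating weights exactly on noiseless data", {
  f <- make_fit_fixture()
  fit <- fit_glm(f$Y, f$dm)
  expect_lt(max(abs(fit$betas - f$B)), 1e-8)
  expect_equal(fit$dof, nrow(f$Y) - ncol(f$dm$X))
  expect_lt(max(abs(fit$residual_variance)), 1e-16)
})

test_that("residuals are orthogonal to every design column", {
  f <- make_fit_fixture(2)
  set.seed(9)
  Y <- f$Y + matrix(rnorm(length(f$Y), sd = 3), nrow(f$Y))
  fit <- fit_glm(Y, f$dm)
  res <- Y - f$dm$X %*% fit$betas
  expect_lt(max(abs(crossprod(f$dm$X, res))), 1e-6 * max(abs(Y)))
})

test_that("contrast t statistics behave correctly at the edges", {
  f <- make_fit_fixture(3)
  set.seed(3)
  Y <- f$Y + matrix(rnorm(length(f$Y)), nrow(f$Y))
  zero_w <- stats::setNames(numeric(ncol(f$dm$X)), colnames(f$dm$X))
  zero_w["trial_1"] <- 0  # contrast of a regressor with itself zeroed
  fit <- fit_glm(Y, f$dm, contrasts = list(null = zero_w,
                                           t1 = c(trial_1 = 1)))
  expect_true(all(fit$contrast_t$null == 0))
  expect_true(all(is.finite(fit$contrast_t$t1)))
  expect_error(fit_glm(Y, f$dm, contrasts = list(bad = c(nope = 1))),
               "unknown regressors")
})

test_that("contrast t is calibrated on pure-noise data", {
  # faces-vs-objects on many independent noise voxels: empirical type-I
  # at p < 0.05 stays near nominal
  d <- generate_localizer_design(seed = 2)
  dm <- build_design_matrix(d, mode = "condition", drift_order = 1)
  set.seed(42)
  n_vox <- 4000
  Y <- matrix(rnorm(d$n_scans * n_vox), d$n_scans, n_vox)
  fit <- fit_glm(Y, dm, contrasts = list(fvo = c(faces = 1, objects = -1)))
  pvals <- 2 * stats::pt(-abs(fit$contrast_t$fvo), fit$dof)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_vox))
})

test_that("singular designs fall back to a pseudo-inverse with a warning", {
  X <- cbind(1, rep(c(0, 1), 10), rep(c(0, 1), 10))
  colnames(X) <- c("c", "a", "b")
  dm <- structure(list(X = X, names = colnames(X),
                       kind = c("constant", "trial", "trial"), tr_s = 2,
                       scan_times = NULL), class = "design_matrix")
  Y <- matrix(rnorm(20), 20, 1)
  expect_warning(fit <- fit_glm(Y, dm), "pseudo-inverse")
  expect_true(all(is.finite(fit$betas)))
})

test_that("trial-beta estimation inverts the noiseless forward model", {
  geom <- reduced_geometry()
  gt <- make_ground_truth("holistic", geom, seed = 4, stability_base = 0.2,
                          stability_effect = 0.5)
  d <- generate_experimental_design(1, 11)
  b <- simulate_behavior(d, seed = 11)
  silent <- noise_model(sigma_thermal = 0, ar1_coef = 0, drift_amp = 0,
                        baseline = 0)
  run <- simulate_bold_run(d, b, gt, silent, seed = 2)
  te <- estimate_trial_betas(run, d, behavior = b)
  A <- run$true_amplitudes
  est <- te$amplitudes[, match(colnames(A), as.character(te$meta$trial_id))]
  expect_lt(max(abs(est - A)), 1e-6)
  expect_equal(te$meta$condition,
               b$condition[match(te$meta$trial_id, b$trial_id)])
  expect_equal(te$meta$response,
               b$response[match(te$meta$trial_id, b$trial_id)])
})

test_that("all-zero data give all-zero betas; voxel order is equivariant", {
  geom <- reduced_geometry()
  gt <- make_ground_truth("null", geom, seed = 5)
  d <- generate_experimental_design(1, 12)
  b <- simulate_behavior(d, seed = 12)
  silent <- noise_model(sigma_thermal = 0, ar1_coef = 0, drift_amp = 0,
                        baseline = 0)
  run <- simulate_bold_run(d, b, gt, silent, seed = 2)
  zero <- run; zero$data <- run$data * 0
  te0 <- estimate_trial_betas(zero, d, behavior = b)
  expect_equal(max(abs(te0$amplitudes)), 0)

  perm <- sample(nrow(run$data))
  shuf <- run; shuf$data <- run$data[perm, ]
  te <- estimate_trial_betas(run, d, behavior = b)
  te_s <- estimate_trial_betas(shuf, d, behavior = b)
  expect_equal(te_s$amplitudes, te$amplitudes[perm, ])
})

test_that("nearly collinear trial regressors are rejected as unestimable", {
  des <- patternsplit:::new_event_design(
    data.frame(onset = c(8, 8.1), duration = c(2, 2),
               condition = c("a", "b"), trial_id = c(1L, 2L),
               stringsAsFactors = FALSE),
    run_id = 1L, tr_s = 2, n_scans = 20L)
  gt <- make_ground_truth("null", reduced_geometry(), seed = 1)
  bold <- patternsplit:::new_bold_run(
    matrix(rnorm(320 * 20), 320, 20), c(8L, 8L, 5L), c(3, 3, 4), 2, 1L)
  expect_error(estimate_trial_betas(bold, des), "collinear")
})
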