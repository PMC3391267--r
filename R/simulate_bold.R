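#' BOLD noise model
#'
#' Additive noise per voxel: an AR(1) process with marginal SD
#' \code{sigma_thermal}, plus a random-slope linear drift of amplitude
#' \code{drift_amp} (peak-to-peak over the run) and a constant baseline.
#'
#' @param sigma_thermal marginal SD of the AR(1) noise, signal units.
#' @param ar1_coef AR(1) coefficient, strictly inside (-1, 1).
#' @param drift_amp scale of the per-run linear drift.
#' @param baseline constant offset added to every voxel.
#' @export
noise_model <- function(sigma_thermal = 6, ar1_coef = 0.3, drift_amp = 2,
                        baseline = 100) {
  if (abs(ar1_coef) >= 1) stop("ar1_coef must lie strictly inside (-1, 1)")
  p <- list(sigma_thermal = sigma_thermal, ar1_coef = ar1_coef,
            drift_amp = drift_amp, baseline = baseline)
  class(p) <- "noise_model"
  p
}

new_bold_run <- function(data, dim, voxel_size_mm, tr_s, run_id) {
  structure(list(data = data, dim = dim, voxel_size_mm = voxel_size_mm,
                 tr_s = tr_s, run_id = run_id),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> run %s: %d voxels (%s grid) x %d scans, TR %g s\n",
              x$run_id, nrow(x$data), paste(x$dim, collapse = "x"),
              ncol(x$data), x$tr_s))
  invisible(x)
}

# scans x voxels matrix of stationary AR(1) noise with marginal SD sigma
ar1_noise <- function(n_vox, n_scans, sigma, phi) {
  innov_sd <- sigma * sqrt(1 - phi^2)
  eps <- matrix(stats::rnorm(n_vox * n_scans, sd = innov_sd), n_scans, n_vox)
  eps[1, ] <- stats::rnorm(n_vox, sd = sigma)
  if (phi == 0) return(eps)
  apply(eps, 2, function(e) stats::filter(e, phi, method = "recursive"))
}

#' Simulate a BOLD run for an event-related experimental design
#'
#' Each voxel's signal is the sum over trials of its true trial amplitude
#' (from the ground truth's stability model) times the HRF-convolved
#' compound-trial boxcar, plus baseline, linear drift with a seeded random
#' slope, and AR(1) noise.  Because the encoding uses the same
#' design-matrix construction as the estimation stage, trial-beta recovery
#' is exact when the noise is switched off.
#'
#' @param design \code{event_design} for the run.
#' @param behavior behavioral records for the run (trial ids must match).
#' @param ground_truth from [make_ground_truth].
#' @param noise a [noise_model].
#' @param seed integer seed.
#' @param params an [hrf_params] list.
#' @param true_amplitudes optionally, a precomputed voxel x trial amplitude
#'   matrix (as from [true_trial_amplitudes]); also returned in the result.
#' @return a \code{bold_run} with \code{data} voxels x scans and the
#'   generating \code{true_amplitudes} attached.
#' @export
simulate_bold_run <- function(design, behavior, ground_truth,
                              noise = noise_model(), seed = 1L,
                              params = hrf_params(),
                              true_amplitudes = NULL) {
  ev_ids <- design$events$trial_id[!is.na(design$events$trial_id)]
  if (!setequal(ev_ids, behavior$trial_id)) {
    stop("design and behavior describe different trial sets")
  }
  gt <- ground_truth
  n_vox <- prod(gt$geometry$dim)
  if (is.null(true_amplitudes)) {
    true_amplitudes <- true_trial_amplitudes(
      gt, behavior, child_seed(seed, "run", design$run_id, "amp"))
  }
  dm <- build_design_matrix(design, params, mode = "trial", drift_order = 0)
  tcol <- which(dm$kind == "trial")
  trial_id <- as.integer(sub("^trial_", "", dm$names[tcol]))
  A <- true_amplitudes[, match(trial_id, colnames(true_amplitudes)),
                       drop = FALSE]
  signal <- dm$X[, tcol, drop = FALSE] %*% t(A)  # scans x voxels
  n_scans <- design$n_scans
  extra <- with_seed(child_seed(seed, "run", design$run_id, "noise"), {
    slopes <- stats::runif(n_vox, -1, 1) * noise$drift_amp
    drift <- outer(seq_len(n_scans) / n_scans - 0.5, slopes)
    nz <- if (noise$sigma_thermal > 0) {
      ar1_noise(n_vox, n_scans, noise$sigma_thermal, noise$ar1_coef)
    } else 0
    drift + nz
  })
  data <- t(signal + extra + noise$baseline)
  colnames(true_amplitudes) <- as.character(colnames(true_amplitudes))
  run <- new_bold_run(data, gt$geometry$dim, gt$geometry$voxel_size_mm,
                      design$tr_s, design$run_id)
  run$true_amplitudes <- true_amplitudes
  run
}

#' Simulate a blocked localizer BOLD run
#'
#' Voxels in face-selective ROIs respond per category with the ground
#' truth's \code{localizer_amplitude}; background voxels respond equally
#' (amplitude 1) to every category, so the faces-vs-objects contrast is
#' selective for the ROIs.
#'
#' @inheritParams simulate_bold_run
#' @param design a localizer \code{event_design}.
#' @export
simulate_localizer_run <- function(design, ground_truth,
                                   noise = noise_model(), seed = 1L,
                                   params = hrf_params()) {
  gt <- ground_truth
  n_vox <- prod(gt$geometry$dim)
  dm <- build_design_matrix(design, params, mode = "condition",
                            drift_order = 0)
  ccol <- which(dm$kind == "condition")
  cats <- dm$names[ccol]
  amp <- matrix(1, n_vox, length(cats), dimnames = list(NULL, cats))
  for (nm in setdiff(names(gt$roi_masks), "background")) {
    la <- gt$localizer_amplitude[cats]
    la[is.na(la)] <- 1
    amp[gt$roi_masks[[nm]], ] <- matrix(la, length(gt$roi_masks[[nm]]),
                                        length(cats), byrow = TRUE)
  }
  signal <- dm$X[, ccol, drop = FALSE] %*% t(amp)
  n_scans <- design$n_scans
  extra <- with_seed(child_seed(seed, "loc", design$run_id, "noise"), {
    slopes <- stats::runif(n_vox, -1, 1) * noise$drift_amp
    drift <- outer(seq_len(n_scans) / n_scans - 0.5, slopes)
    nz <- if (noise$sigma_thermal > 0) {
      ar1_noise(n_vox, n_scans, noise$sigma_thermal, noise$ar1_coef)
    } else 0
    drift + nz
  })
  new_bold_run(t(signal + extra + noise$baseline), gt$geometry$dim,
               gt$geometry$voxel_size_mm, design$tr_s, design$run_id)
}

#' Write / read a BOLD run as a NIfTI-1 4-D volume
#'
#' The voxel x scan matrix is reshaped to the grid's 4-D array; TR is
#' stored in the NIfTI header's time pixdim.
#'
#' @param bold_run a \code{bold_run}.
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @export
write_bold_nifti <- function(bold_run, path) {
  arr <- array(bold_run$data, c(bold_run$dim, ncol(bold_run$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(bold_run$voxel_size_mm, bold_run$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param run_id run index to attach to the loaded run.
#' @export
read_bold_nifti <- function(path, run_id = 1L) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  data <- matrix(img, prod(d[1:3]), d[4])
  new_bold_run(data, d[1:3], pd[1:3], pd[4], run_id)
}
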