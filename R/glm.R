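pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit a run-level general linear model by ordinary least squares
#'
#' Per-voxel OLS of the BOLD time courses on the design matrix.  Contrast
#' t statistics are \eqn{t = c'\beta / \sqrt{\hat\sigma^2 c'(X'X)^{-1}c}}
#' with \eqn{\hat\sigma^2} the residual variance on \code{dof} degrees of
#' freedom (scans minus design rank).  Singular normal equations fall back
#' to the Moore-Penrose pseudo-inverse with a warning.
#'
#' @param bold_run a \code{bold_run} (or a scans x voxels matrix).
#' @param design_matrix a \code{design_matrix} from [build_design_matrix].
#' @param contrasts optional named list of contrast weight vectors, each of
#'   length \code{ncol(X)} or named by regressor.
#' @return a \code{glm_fit}: \code{betas} (regressors x voxels),
#'   \code{residual_variance}, \code{dof}, and per-contrast \code{t}
#'   (voxel vectors in \code{contrast_t}).
#' @export
fit_glm <- function(bold_run, design_matrix, contrasts = NULL) {
  X <- design_matrix$X
  Y <- if (inherits(bold_run, "bold_run")) t(bold_run$data) else bold_run
  if (nrow(Y) != nrow(X)) stop("scan count differs between data and design")
  qrX <- qr(X)
  rank <- qrX$rank
  singular <- rank < ncol(X)
  if (singular) {
    warning("singular normal equations; using pseudo-inverse")
    XtXinv <- pinv(crossprod(X))
    betas <- XtXinv %*% crossprod(X, Y)
  } else {
    betas <- qr.coef(qrX, Y)
    XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
  }
  betas[is.na(betas)] <- 0
  fitted <- X %*% betas
  res <- Y - fitted
  dof <- nrow(Y) - rank
  sigma2 <- colSums(res^2) / dof
  contrast_t <- NULL
  if (!is.null(contrasts)) {
    contrast_t <- lapply(contrasts, function(w) {
      cv <- expand_contrast(w, colnames(X))
      num <- drop(crossprod(cv, betas))
      den <- sqrt(sigma2 * drop(t(cv) %*% XtXinv %*% cv))
      ifelse(den > 0, num / den, 0)
    })
  }
  structure(list(betas = betas, residual_variance = sigma2, dof = dof,
                 contrast_t = contrast_t, design = design_matrix),
            class = "glm_fit")
}

# contrast given as full-length vector, or named weights over regressors
expand_contrast <- function(w, reg_names) {
  if (!is.null(names(w))) {
    cv <- stats::setNames(rep(0, length(reg_names)), reg_names)
    unknown <- setdiff(names(w), reg_names)
    if (length(unknown) > 0) stop("unknown regressors in contrast: ",
                                  paste(unknown, collapse = ", "))
    cv[names(w)] <- w
    cv
  } else {
    if (length(w) != length(reg_names)) stop("contrast length mismatch")
    w
  }
}

new_trial_estimates <- function(amplitudes, meta, voxel_indices = NULL) {
  stopifnot(ncol(amplitudes) == nrow(meta))
  if (is.null(voxel_indices)) voxel_indices <- seq_len(nrow(amplitudes))
  stopifnot(length(voxel_indices) == nrow(amplitudes))
  structure(list(amplitudes = amplitudes, meta = meta,
                 voxel_indices = voxel_indices),
            class = "trial_estimates")
}

#' Rows of a trial-estimate matrix corresponding to grid voxel indices
#'
#' @param trial_estimates a \code{trial_estimates}.
#' @param voxels grid voxel indices (or an \code{roi_mask}).
#' @return integer row indices into \code{amplitudes}; errors if any voxel
#'   was not estimated.
#' @export
roi_rows <- function(trial_estimates, voxels) {
  if (inherits(voxels, "roi_mask")) voxels <- voxels$voxel_indices
  rows <- match(voxels, trial_estimates$voxel_indices)
  if (anyNA(rows)) stop("some requested voxels were not estimated")
  rows
}

#' @export
print.trial_estimates <- function(x, ...) {
  cat(sprintf("<trial_estimates> %d voxels x %d trials (%d runs)\n",
              nrow(x$amplitudes), ncol(x$amplitudes),
              length(unique(x$meta$run_id))))
  invisible(x)
}

#' Estimate trial-wise response amplitudes (least-squares-all)
#'
#' Fits one GLM per run in which every face-pair trial has its own
#' HRF-convolved regressor, alongside polynomial drift and a constant
#' ("least-squares-all" single-trial estimation).  The per-trial betas are
#' the voxelwise response amplitudes to each compound trial.
#'
#' Pairs of trial regressors correlated above \code{max_collinearity} make
#' the trial amplitudes unestimable and raise an error.
#'
#' @param bold_run a \code{bold_run}.
#' @param design the run's \code{event_design}.
#' @param params an [hrf_params] list.
#' @param behavior optional behavioral records; when given, each trial is
#'   labelled with its response.
#' @param drift_order polynomial drift order for the run GLM.
#' @param mask optional voxel indices to restrict estimation to.
#' @param max_collinearity maximum tolerated |r| between trial regressors.
#' @return a \code{trial_estimates}: \code{amplitudes} (voxels x trials)
#'   and \code{meta} (trial_id, run_id, condition, response).
#' @export
estimate_trial_betas <- function(bold_run, design, params = hrf_params(),
                                 behavior = NULL, drift_order = 1,
                                 mask = NULL, max_collinearity = 0.99) {
  dm <- build_design_matrix(design, params, mode = "trial",
                            drift_order = drift_order)
  tcol <- which(dm$kind == "trial")
  if (length(tcol) >= 2) {
    R <- stats::cor(dm$X[, tcol, drop = FALSE])
    off <- abs(R[upper.tri(R)])
    if (any(off > max_collinearity)) {
      stop(sprintf("trial regressors nearly collinear (max |r| = %.4f); trial amplitudes unestimable",
                   max(off)))
    }
  }
  Y <- t(bold_run$data)
  if (!is.null(mask)) Y <- Y[, mask, drop = FALSE]
  fit <- fit_glm(Y, dm)
  amp <- fit$betas[tcol, , drop = FALSE]
  trial_id <- as.integer(sub("^trial_", "", dm$names[tcol]))
  ev <- design$events[!is.na(design$events$trial_id), , drop = FALSE]
  meta <- data.frame(trial_id = trial_id,
                     run_id = design$run_id,
                     condition = ev$condition[match(trial_id, ev$trial_id)],
                     response = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(behavior)) {
    meta$response <- behavior$response[match(trial_id, behavior$trial_id)]
  }
  new_trial_estimates(t(amp), meta,
                      voxel_indices = if (is.null(mask)) {
                        seq_len(nrow(bold_run$data))
                      } else mask)
}

#' Combine trial estimates across runs
#'
#' @param ... \code{trial_estimates} objects (or one list of them).
#' @return a single \code{trial_estimates} with trials concatenated.
#' @export
combine_trial_estimates <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "trial_estimates")) xs <- xs[[1]]
  vi <- xs[[1]]$voxel_indices
  for (x in xs[-1]) {
    if (!identical(x$voxel_indices, vi)) stop("runs cover different voxel sets")
  }
  new_trial_estimates(do.call(cbind, lapply(xs, `[[`, "amplitudes")),
                      do.call(rbind, lapply(xs, `[[`, "meta")),
                      voxel_indices = vi)
}
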