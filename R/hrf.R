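#' Gamma hemodynamic response function parameters
#'
#' The gamma HRF \eqn{h(t) = ((t-\delta)/\tau)^\alpha e^{-(t-\delta)/\tau}}
#' for \eqn{t > \delta} (0 before), peak-normalized to 1.  Defaults are the
#' FS-FAST convention: onset delay \eqn{\delta = 2.25} s, dispersion
#' \eqn{\tau = 1.25} s, shape exponent \eqn{\alpha = 2}, giving a peak at
#' \eqn{\delta + \alpha\tau = 4.75} s.
#'
#' @param delta_s onset delay in seconds (>= 0).
#' @param tau_s dispersion in seconds (> 0).
#' @param alpha shape exponent (> 0).
#' @export
hrf_params <- function(delta_s = 2.25, tau_s = 1.25, alpha = 2) {
  stopifnot(delta_s >= 0, tau_s > 0, alpha > 0)
  p <- list(delta_s = delta_s, tau_s = tau_s, alpha = alpha)
  class(p) <- "hrf_params"
  p
}

#' Evaluate the gamma HRF on a time grid
#'
#' @param time_grid non-negative, increasing times in seconds.
#' @param params an [hrf_params] list.
#' @return amplitudes, peak-normalized so the maximum over all t is 1.
#' @examples
#' gamma_hrf(c(2.25, 4.75), hrf_params())  # 0 at onset, 1 at peak
#' @export
gamma_hrf <- function(time_grid, params = hrf_params()) {
  x <- (time_grid - params$delta_s) / params$tau_s
  h <- ifelse(x > 0, x^params$alpha * exp(-x), 0)
  peak <- params$alpha^params$alpha * exp(-params$alpha)
  h / peak
}

#' Build a GLM design matrix from an event design
#'
#' Each regressor is a boxcar convolved with the gamma HRF on an
#' oversampled grid (default 0.1 s) and sampled at scan acquisition times
#' \code{(k + 0.5) * TR}.  In \code{mode = "trial"} every non-fixation
#' trial gets its own column (in trial-id order); in
#' \code{mode = "condition"} one column per non-fixation condition.
#' Polynomial drift columns up to \code{drift_order} and a constant are
#' appended.
#'
#' For the paired-image face trials (conditions \code{veridical} /
#' \code{scrambled}) the boxcar spans the stimulation window of the
#' compound trial — from first-image onset at trial start + 0.7 s to
#' second-image offset at trial start + 2.2 s (1.5 s) — rather than the
#' full 4-s trial; \code{stim_window} exposes this choice.  All other
#' event types use their full duration.
#'
#' @param design an \code{event_design}.
#' @param params an [hrf_params] list.
#' @param mode \code{"trial"} or \code{"condition"}.
#' @param drift_order highest polynomial drift order (0 = constant only).
#' @param stim_window c(offset from trial onset, boxcar duration) in
#'   seconds for compound face trials.
#' @param oversample_s resolution of the convolution grid, seconds.
#' @return a \code{design_matrix}: scans x regressors matrix \code{X},
#'   \code{names}, and per-column \code{kind} in trial / condition /
#'   drift / constant.
#' @export
build_design_matrix <- function(design, params = hrf_params(),
                                mode = c("trial", "condition"),
                                drift_order = 1,
                                stim_window = c(0.7, 1.5),
                                oversample_s = 0.1) {
  mode <- match.arg(mode)
  dt <- oversample_s
  n_scans <- design$n_scans
  span <- n_scans * design$tr_s
  n_grid <- round(span / dt)
  ev <- design$events[design$events$condition != "fixation", , drop = FALSE]

  kern_t <- seq(0, 32, by = dt)
  kern <- gamma_hrf(kern_t, params)

  windowed <- function(onset, duration, condition) {
    if (condition %in% c("veridical", "scrambled")) {
      c(onset + stim_window[1], stim_window[2])
    } else {
      c(onset, duration)
    }
  }
  # response of a boxcar of `dur` seconds starting at grid index 1
  shape_cache <- new.env(parent = emptyenv())
  boxcar_response <- function(dur) {
    key <- format(dur, digits = 12)
    if (!is.null(shape_cache[[key]])) return(shape_cache[[key]])
    box <- rep(1, max(1L, round(dur / dt)))
    sh <- stats::convolve(box, rev(kern), type = "open") * dt
    shape_cache[[key]] <- sh
    sh
  }
  column_for <- function(rows) {
    col <- numeric(n_grid)
    for (i in rows) {
      w <- windowed(ev$onset[i], ev$duration[i], ev$condition[i])
      sh <- boxcar_response(w[2])
      start <- round(w[1] / dt) + 1L
      idx <- start:min(n_grid, start + length(sh) - 1L)
      if (start <= n_grid) col[idx] <- col[idx] + sh[seq_along(idx)]
    }
    col
  }

  if (mode == "trial") {
    ord <- order(ev$trial_id)
    cols <- lapply(ord, function(i) column_for(i))
    nms <- if (length(ord) > 0) paste0("trial_", ev$trial_id[ord]) else character(0)
    kind <- rep("trial", length(cols))
  } else {
    conds <- unique(ev$condition)
    cols <- lapply(conds, function(cc) column_for(which(ev$condition == cc)))
    nms <- conds
    kind <- rep("condition", length(cols))
  }

  scan_t <- (seq_len(n_scans) - 0.5) * design$tr_s
  scan_idx <- round(scan_t / dt) + 1L  # grid index of time (k+0.5)*TR
  X <- if (length(cols) > 0) {
    do.call(cbind, lapply(cols, function(cc) cc[scan_idx]))
  } else {
    matrix(0, n_scans, 0)
  }

  if (drift_order > 0 && n_scans > drift_order) {
    dr <- stats::poly(seq_len(n_scans), degree = drift_order)
    X <- cbind(X, dr)
    nms <- c(nms, paste0("drift_", seq_len(drift_order)))
    kind <- c(kind, rep("drift", drift_order))
  }
  X <- cbind(X, 1)
  nms <- c(nms, "constant")
  kind <- c(kind, "constant")
  colnames(X) <- nms

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning(sprintf("design matrix is rank deficient (rank %d of %d columns); condition number %.3g",
                    qrX$rank, ncol(X), kappa(X)))
  }
  structure(list(X = X, names = nms, kind = kind, tr_s = design$tr_s,
                 scan_times = scan_t),
            class = "design_matrix")
}
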