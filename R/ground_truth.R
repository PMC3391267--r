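#' Voxel-grid geometry for the synthetic cohort
#'
#' A single 3-D grid holds all simulated voxels; regions of interest are
#' compact ellipsoidal blobs of a fixed voxel count.  Defaults give a
#' 20 x 20 x 10 grid of 3 x 3 x 4 mm voxels with a 28-voxel face-selective
#' fusiform-like ROI and a 32-voxel occipital-like ROI, voxel counts in the
#' range typically reported for individually localized FFA/OFA.
#'
#' @param dim integer grid dimensions (x, y, z).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param rois named list; each entry a list with \code{center} (grid
#'   coordinates) and \code{n_voxels}.
#' @export
geometry_params <- function(dim = c(20L, 20L, 10L),
                            voxel_size_mm = c(3, 3, 4),
                            rois = list(
                              ffa_like = list(center = c(6, 7, 4), n_voxels = 28L),
                              ofa_like = list(center = c(15, 14, 6), n_voxels = 32L))) {
  g <- list(dim = as.integer(dim), voxel_size_mm = voxel_size_mm, rois = rois)
  class(g) <- "geometry_params"
  g
}

#' Reduced single-ROI geometry for large simulation studies
#'
#' An 8 x 8 x 5 grid containing only the 28-voxel fusiform-like ROI; used
#' for calibration and power studies where thousands of cohorts are drawn.
#'
#' @export
reduced_geometry <- function() {
  geometry_params(dim = c(8L, 8L, 5L), voxel_size_mm = c(3, 3, 4),
                  rois = list(ffa_like = list(center = c(4, 4, 3),
                                              n_voxels = 28L)))
}

# Compact blob: the n voxels closest (in mm) to the ROI center.
roi_blob <- function(dim, voxel_size_mm, center, n_voxels) {
  grid <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                                z = seq_len(dim[3])))
  d2 <- colSums((t(grid) - center)^2 * voxel_size_mm^2)
  sort(order(d2)[seq_len(n_voxels)])
}

scenario_names <- c("holistic", "parts_based", "both", "null")
cell_names <- c("veridical.correct", "veridical.incorrect",
                "scrambled.correct", "scrambled.incorrect")

# Stability of the four stimulus x response cells for one ROI.
# `kind` is the representational scheme the ROI carries.
stability_table <- function(kind, base, effect) {
  s <- stats::setNames(rep(base, 4), cell_names)
  if (kind == "holistic") {
    s["veridical.correct"] <- base + effect
  } else if (kind == "parts_based") {
    s["veridical.correct"] <- base + effect
    s["scrambled.correct"] <- base + effect
  } else if (kind == "both") {
    s["veridical.correct"] <- base + effect
    s["scrambled.correct"] <- base + effect / 2
  } else if (kind != "null") {
    stop("unknown representation kind: ", kind)
  }
  if (any(s < 0 | s > 1)) stop("stability values must lie in [0, 1]")
  s
}

#' Ground truth for one synthetic subject
#'
#' Draws, once per subject, the true spatial activation pattern of every
#' stimulus x response cell in every ROI, and fixes the per-cell pattern
#' stability that governs across-trial (hence across-half) reliability.
#' The scenario names the representational scheme of the fusiform-like ROI:
#' \describe{
#'   \item{holistic}{correct trials are more stable than incorrect trials
#'     for veridical faces only (configuration-dependent readout).}
#'   \item{parts_based}{correct trials are more stable for both veridical
#'     and scrambled faces (configuration-independent readout).}
#'   \item{both}{the full effect for veridical plus half the effect for
#'     scrambled faces.}
#'   \item{null}{no reproducible pattern component in any cell: all
#'     stabilities equal the base (default 0), so split-half correlations
#'     are centered on zero for every cell whatever the trial counts.}
#' }
#' Any occipital-like ROI present in the geometry carries a parts-based
#' table under every non-null scenario, mirroring the functional division
#' of labor the pipeline is designed to detect; under \code{null} every ROI
#' is null.
#'
#' @param scenario one of \code{"holistic"}, \code{"parts_based"},
#'   \code{"both"}, \code{"null"}.
#' @param geometry a [geometry_params] list.
#' @param seed integer seed (per subject).
#' @param stability_base stability of unaffected cells, in [0, 1].
#' @param stability_effect stability increment of affected correct cells.
#' @param pattern_mean named mean true amplitude per condition; the default
#'   scrambled/veridical ratio of 0.93 reproduces the near-equal mean
#'   responses to the two stimulus types.
#' @param pattern_sd across-voxel SD of the true cell patterns.
#' @param trial_noise_sd SD of the i.i.d. per-trial pattern perturbation.
#' @param localizer_amplitude named response amplitude per localizer
#'   category for face-selective ROI voxels; background voxels respond
#'   equally (amplitude 1) to every category.
#' @return a \code{ground_truth} list: roi_masks (named voxel-index sets,
#'   plus \code{background}), per-ROI \code{patterns} (voxel x cell),
#'   \code{stability} (ROI x cell), scenario and noise parameters.
#' @export
make_ground_truth <- function(scenario = c("holistic", "parts_based", "both", "null"),
                              geometry = geometry_params(), seed = 1L,
                              stability_base = 0, stability_effect = 0.7,
                              pattern_mean = c(veridical = 1, scrambled = 0.93),
                              pattern_sd = 1, trial_noise_sd = 1,
                              localizer_amplitude = c(faces = 2, objects = 1,
                                                      houses = 1,
                                                      scrambled_objects = 0.8)) {
  scenario <- match.arg(scenario)
  g <- geometry
  n_vox <- prod(g$dim)
  masks <- lapply(g$rois, function(r) {
    roi_blob(g$dim, g$voxel_size_mm, r$center, r$n_voxels)
  })
  all_idx <- unlist(masks)
  if (anyDuplicated(all_idx)) stop("requested ROIs overlap; move centers apart")
  masks$background <- setdiff(seq_len(n_vox), all_idx)

  roi_kind <- function(name) {
    if (scenario == "null") return("null")
    if (name == "ffa_like") scenario else "parts_based"
  }
  analysed <- setdiff(names(masks), "background")
  stability <- do.call(rbind, lapply(analysed, function(nm) {
    stability_table(roi_kind(nm), stability_base, stability_effect)
  }))
  rownames(stability) <- analysed

  patterns <- with_seed(child_seed(seed, "ground_truth"), {
    out <- lapply(analysed, function(nm) {
      nv <- length(masks[[nm]])
      p <- matrix(stats::rnorm(nv * 4, sd = pattern_sd), nv, 4,
                  dimnames = list(NULL, cell_names))
      cond <- sub("\\..*$", "", cell_names)
      sweep(p, 2, pattern_mean[cond], `+`)
    })
    stats::setNames(out, analysed)
  })

  structure(list(roi_masks = masks, patterns = patterns,
                 stability = stability, scenario = scenario,
                 geometry = g, pattern_mean = pattern_mean,
                 pattern_sd = pattern_sd, trial_noise_sd = trial_noise_sd,
                 localizer_amplitude = localizer_amplitude,
                 seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> scenario '%s', grid %s, ROIs: %s\n",
              x$scenario, paste(x$geometry$dim, collapse = "x"),
              paste(sprintf("%s (%d vox)",
                            setdiff(names(x$roi_masks), "background"),
                            vapply(x$roi_masks[setdiff(names(x$roi_masks),
                                                       "background")],
                                   length, 1L)),
                    collapse = ", ")))
  invisible(x)
}

#' True trial amplitudes for one run under the stability model
#'
#' The amplitude of voxel v on a trial in cell c is the convex mixture
#' \code{s_c * pattern[v, c] + (1 - s_c) * eps}, with eps i.i.d. Gaussian
#' per trial and voxel: the stability \code{s_c} sets how much of the
#' cell's fixed pattern recurs from trial to trial.  Background voxels
#' carry pure per-trial noise.
#'
#' @param ground_truth from [make_ground_truth].
#' @param behavior behavioral records for the run's trials.
#' @param seed integer seed.
#' @return matrix voxels (full grid) x trials, columns named by trial_id.
#' @export
true_trial_amplitudes <- function(ground_truth, behavior, seed) {
  gt <- ground_truth
  n_vox <- prod(gt$geometry$dim)
  n_tr <- nrow(behavior)
  cellf <- paste(behavior$condition,
                 ifelse(behavior$response == "none", "correct", behavior$response),
                 sep = ".")
  amp <- matrix(0, n_vox, n_tr, dimnames = list(NULL, behavior$trial_id))
  with_seed(child_seed(seed, "amplitudes"), {
    for (nm in setdiff(names(gt$roi_masks), "background")) {
      vox <- gt$roi_masks[[nm]]
      s <- gt$stability[nm, cellf]
      eps <- matrix(stats::rnorm(length(vox) * n_tr, sd = gt$trial_noise_sd),
                    length(vox), n_tr)
      amp[vox, ] <- sweep(gt$patterns[[nm]][, cellf, drop = FALSE], 2, s, `*`) +
        sweep(eps, 2, 1 - s, `*`)
    }
    bg <- gt$roi_masks$background
    if (length(bg) > 0) {
      amp[bg, ] <- stats::rnorm(length(bg) * n_tr, sd = gt$trial_noise_sd)
    }
  })
  amp
}
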