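#' Drop trials without a behavioral response
#'
#' @param trial_estimates a \code{trial_estimates}.
#' @return the same object with \code{response == "none"} trials removed;
#'   the number dropped is reported via \code{message}.
#' @export
filter_trials <- function(trial_estimates) {
  te <- trial_estimates
  keep <- te$meta$response != "none" & !is.na(te$meta$response)
  if (!any(keep)) stop("all trials lack a response; nothing to analyze")
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("excluding %d of %d trials with no response",
                    n_drop, length(keep)))
  }
  new_trial_estimates(te$amplitudes[, keep, drop = FALSE],
                      te$meta[keep, , drop = FALSE], te$voxel_indices)
}

split_cells <- function(meta) {
  half <- ifelse(meta$run_id %% 2 == 1, "odd", "even")
  cell <- paste(meta$condition, meta$response, sep = ".")
  list(half = half, cell = cell)
}

#' Behavior-sorted odd/even split-half pattern correlations for one ROI
#'
#' The session's runs are split by parity of their 1-based index into odd
#' and even halves.  Within each half, trial amplitudes are averaged per
#' stimulus x response cell over the ROI's voxels; each voxel's mean
#' across the four cells is then subtracted within that half
#' (cocktail-blank centering); finally the odd and even centered vectors of
#' the same cell are Pearson-correlated, giving four correlations per
#' subject and ROI.
#'
#' A cell with no trials in one half, or with a zero-variance centered
#' vector, yields \code{NA} with a flag rather than a silent zero; such
#' subjects are excluded from the affected group contrast downstream.
#'
#' @param trial_estimates a \code{trial_estimates} (after [filter_trials]).
#' @param roi_mask an \code{roi_mask}, or an integer vector of voxel row
#'   indices into the amplitude matrix.
#' @param centering subtract the per-voxel cell mean within each half
#'   (default TRUE).
#' @param fisher_z return Fisher z-transformed correlations (default FALSE).
#' @return a \code{split_half_result}: data frame with condition, response,
#'   r, n_odd, n_even, flag.
#' @export
split_half_correlations <- function(trial_estimates, roi_mask,
                                    centering = TRUE, fisher_z = FALSE) {
  te <- trial_estimates
  vox <- if (inherits(roi_mask, "roi_mask")) roi_rows(te, roi_mask) else roi_mask
  if (length(vox) < 2) stop("ROI must contain at least 2 voxels")
  amp <- te$amplitudes[vox, , drop = FALSE]
  sc <- split_cells(te$meta)
  cells <- cell_names[cell_names %in% unique(sc$cell)]

  half_patterns <- function(which_half) {
    in_half <- sc$half == which_half
    m <- vapply(cells, function(cl) {
      cols <- in_half & sc$cell == cl
      if (!any(cols)) return(rep(NA_real_, length(vox)))
      rowMeans(amp[, cols, drop = FALSE])
    }, numeric(length(vox)))
    if (centering) {
      ok <- colSums(is.na(m)) == 0
      if (any(ok)) m <- m - rowMeans(m[, ok, drop = FALSE])
    }
    m
  }
  odd <- half_patterns("odd")
  even <- half_patterns("even")
  counts <- function(which_half, cl) sum(sc$half == which_half & sc$cell == cl)

  rs <- numeric(length(cells)); flags <- character(length(cells))
  for (i in seq_along(cells)) {
    x <- odd[, i]; y <- even[, i]
    if (anyNA(x) || anyNA(y)) {
      flags[i] <- "empty_cell"; rs[i] <- NA_real_
    } else if (stats::var(x) == 0 || stats::var(y) == 0) {
      flags[i] <- "zero_variance"; rs[i] <- NA_real_
    } else {
      rs[i] <- stats::cor(x, y)
      if (fisher_z) rs[i] <- atanh(rs[i])
      flags[i] <- "ok"
    }
  }
  parts <- strsplit(cells, ".", fixed = TRUE)
  res <- data.frame(
    condition = vapply(parts, `[`, "", 1),
    response = vapply(parts, `[`, "", 2),
    r = rs,
    n_odd = vapply(cells, function(cl) counts("odd", cl), 0L),
    n_even = vapply(cells, function(cl) counts("even", cl), 0L),
    flag = flags, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("split_half_result", "data.frame"),
            fisher_z = fisher_z)
}

#' Equalize correct/incorrect trial counts between stimulus conditions
#'
#' Within each response type and each half of the data, the condition with
#' more trials is randomly subsampled (seeded) down to the other
#' condition's count — the matched-trial control for trial-count-dependent
#' reliability.  The subsample is drawn once per seed.
#'
#' @param trial_estimates a \code{trial_estimates}.
#' @param seed integer seed.
#' @return a \code{trial_estimates} with matched counts; cells with zero
#'   trials are left unmatched with a warning.
#' @export
match_trial_counts <- function(trial_estimates, seed = 1L) {
  te <- trial_estimates
  sc <- split_cells(te$meta)
  keep <- logical(ncol(te$amplitudes))
  with_seed(child_seed(seed, "match"), {
    for (h in unique(sc$half)) {
      for (resp in unique(te$meta$response)) {
        sel <- lapply(c("veridical", "scrambled"), function(cond) {
          which(sc$half == h & te$meta$response == resp &
                  te$meta$condition == cond)
        })
        n <- vapply(sel, length, 1L)
        if (any(n == 0)) {
          if (any(n > 0)) {
            warning(sprintf("half %s, response %s: a condition has no trials; left unmatched",
                            h, resp))
            keep[unlist(sel)] <- TRUE
          }
          next
        }
        target <- min(n)
        for (s in sel) {
          keep[if (length(s) > target) sort(sample(s, target)) else s] <- TRUE
        }
      }
    }
  })
  new_trial_estimates(te$amplitudes[, keep, drop = FALSE],
                      te$meta[keep, , drop = FALSE], te$voxel_indices)
}

#' Mean ROI response magnitude per stimulus x response cell
#'
#' The conventional univariate summary: the grand mean amplitude over the
#' ROI's voxels and all of a cell's trials (both halves pooled).
#'
#' @param trial_estimates a \code{trial_estimates}.
#' @param roi_mask an \code{roi_mask} or voxel index vector.
#' @return data frame: condition, response, mean_amplitude, n_trials; cells
#'   without trials appear with \code{NA} and are flagged.
#' @export
roi_mean_magnitude <- function(trial_estimates, roi_mask) {
  te <- trial_estimates
  vox <- if (inherits(roi_mask, "roi_mask")) roi_rows(te, roi_mask) else roi_mask
  amp <- te$amplitudes[vox, , drop = FALSE]
  cell <- paste(te$meta$condition, te$meta$response, sep = ".")
  res <- do.call(rbind, lapply(cell_names, function(cl) {
    cols <- cell == cl
    parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
    data.frame(condition = parts[1], response = parts[2],
               mean_amplitude = if (any(cols)) mean(amp[, cols]) else NA_real_,
               n_trials = sum(cols),
               flag = if (any(cols)) "ok" else "empty_cell",
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Export split-half results as a tidy tab-separated table
#'
#' One row per subject x ROI x condition x response with columns subject,
#' roi, condition, response, r, n_odd, n_even.
#'
#' @param results named list (by subject) of named lists (by ROI) of
#'   \code{split_half_result} objects, or a prebuilt data frame.
#' @param path output path.
#' @export
write_split_half_tsv <- function(results, path) {
  df <- if (is.data.frame(results)) results else tidy_split_half(results)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tidy_split_half <- function(results) {
  do.call(rbind, lapply(names(results), function(subj) {
    do.call(rbind, lapply(names(results[[subj]]), function(roi) {
      r <- results[[subj]][[roi]]
      cbind(data.frame(subject = subj, roi = roi, stringsAsFactors = FALSE),
            as.data.frame(r)[, c("condition", "response", "r",
                                 "n_odd", "n_even")])
    }))
  }))
}
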