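#' Smooth a 3-D volume with a separable Gaussian kernel
#'
#' Kernel SD per axis is \code{fwhm_mm / (2 sqrt(2 ln 2))} converted to
#' voxel units.  Edges are handled by renormalizing the kernel mass inside
#' the volume, so constant volumes are preserved exactly.  A FWHM of 0
#' returns the input unchanged.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm full width at half maximum, mm (default 5).
#' @param voxel_size_mm voxel edge lengths, mm.
#' @return smoothed array, same dimensions.
#' @export
smooth_volume <- function(volume, fwhm_mm = 5, voxel_size_mm = c(3, 3, 4)) {
  stopifnot(fwhm_mm >= 0, length(dim(volume)) == 3)
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  out <- volume
  norm <- array(1, dim(volume))
  for (ax in 1:3) {
    r <- max(1L, ceiling(3 * sigma_vox[ax]))
    k <- stats::dnorm(seq(-r, r), sd = sigma_vox[ax])
    k <- k / sum(k)
    out <- conv_axis(out, k, ax)
    norm <- conv_axis(norm, k, ax)
  }
  out / norm
}

# zero-padded convolution of a 3-D array along one axis
conv_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) / 2L
  d <- dim(a)
  res <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(d[axis]) + off
    ok <- src >= 1L & src <= d[axis]
    if (!any(ok)) next
    dst <- which(ok)
    idx_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_dst <- idx_src
    idx_src[[axis]] <- src[ok]
    idx_dst[[axis]] <- dst
    res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      k[j] * a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  res
}

neighbor_offsets <- function(connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  off
}

# label connected components of a logical 3-D mask; 0 = background
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- neighbor_offsets(connectivity)
  labels <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, d)
      nb <- sweep(off, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[mask[lin] & labels[lin] == 0L]
      labels[new] <- nxt
      queue <- c(queue, new)
    }
  }
  labels
}

#' Define a region of interest from a localizer contrast map
#'
#' Thresholds the t map at the one-tailed t quantile for
#' \code{p_threshold} on \code{dof} degrees of freedom (the contrast is
#' directional: larger responses to the preferred category), labels
#' connected components (26-neighborhood by default), and returns the
#' component of at least \code{min_size} voxels that contains the seed
#' coordinate, or failing that the one nearest to it.  When nothing
#' survives, an empty mask is returned (see [roi_is_empty]) so the caller
#' can exclude the subject, as is done when a region cannot be localized.
#'
#' @param t_map 3-D array of contrast t values.
#' @param dof residual degrees of freedom of the contrast.
#' @param p_threshold one-tailed uncorrected significance level
#'   (default 0.01).
#' @param component_seed grid coordinate (x, y, z) expected inside the ROI.
#' @param min_size minimum component size in voxels.
#' @param connectivity 6 or 26.
#' @param name label for the mask.
#' @return an \code{roi_mask}: sorted voxel indices, name, threshold used.
#' @export
define_roi <- function(t_map, dof, p_threshold = 0.01, component_seed,
                       min_size = 1L, connectivity = 26, name = "roi") {
  thr <- stats::qt(1 - p_threshold, dof)
  mask <- t_map > thr
  labels <- label_components(mask, connectivity)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_size)
  empty <- structure(list(voxel_indices = integer(0), name = name,
                          threshold_p = p_threshold, threshold_t = thr,
                          component_seed = component_seed,
                          dim = dim(t_map)),
                     class = "roi_mask")
  if (length(keep) == 0) return(empty)
  d <- dim(t_map)
  seed_lin <- component_seed[1] + (component_seed[2] - 1L) * d[1] +
    (component_seed[3] - 1L) * d[1] * d[2]
  chosen <- if (labels[seed_lin] %in% keep) {
    labels[seed_lin]
  } else {
    dists <- vapply(keep, function(lb) {
      co <- arrayInd(which(labels == lb), d)
      min(sqrt(colSums((t(co) - component_seed)^2)))
    }, 0)
    keep[which.min(dists)]
  }
  structure(list(voxel_indices = sort(which(labels == chosen)), name = name,
                 threshold_p = p_threshold, threshold_t = thr,
                 component_seed = component_seed, dim = d),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels (p < %g one-tailed, t > %.3f)\n",
              x$name, length(x$voxel_indices), x$threshold_p, x$threshold_t))
  invisible(x)
}

#' Is an ROI mask empty (region not localizable)?
#' @param roi an \code{roi_mask}.
#' @export
roi_is_empty <- function(roi) length(roi$voxel_indices) == 0

#' Dice overlap between two voxel index sets
#'
#' @param a,b integer index vectors (or \code{roi_mask} objects).
#' @return \eqn{2|a \cap b| / (|a| + |b|)}.
#' @export
dice_overlap <- function(a, b) {
  if (inherits(a, "roi_mask")) a <- a$voxel_indices
  if (inherits(b, "roi_mask")) b <- b$voxel_indices
  if (length(a) + length(b) == 0) return(NA_real_)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Write / read an ROI mask as a JSON index list or NIfTI volume
#'
#' @param roi an \code{roi_mask}.
#' @param path output path; \code{.json} gives a plain index list,
#'   \code{.nii}/\code{.nii.gz} a binary volume.
#' @export
write_roi_mask <- function(roi, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(name = roi$name, dim = roi$dim, threshold_p = roi$threshold_p,
           voxel_indices = roi$voxel_indices),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    vol <- array(0L, roi$dim)
    vol[roi$voxel_indices] <- 1L
    RNifti::writeNifti(RNifti::asNifti(vol), path)
  }
  invisible(path)
}
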