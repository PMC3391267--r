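#' Default pipeline configuration
#'
#' A nested list with every tunable of the pipeline; [run_pipeline]
#' validates user configs against this template (unknown keys are
#' rejected).  A machine-readable description of the schema ships in
#' \code{inst/extdata/config-schema.json}.
#'
#' @param master_seed master seed for all randomness.
#' @param n_subjects cohort size.
#' @param n_runs experimental runs per subject.
#' @param scenario representational scenario, see [make_ground_truth].
#' @param output_dir where [run_pipeline] writes its artifacts.
#' @param level \code{"bold"} (full time-series simulation and GLM) or
#'   \code{"amplitude"} (trial-amplitude shortcut).
#' @export
default_config <- function(master_seed = 1L, n_subjects = 13L, n_runs = 10L,
                           scenario = "holistic", output_dir = "patternsplit_out",
                           level = "bold") {
  list(
    master_seed = master_seed,
    n_subjects = n_subjects,
    n_runs = n_runs,
    scenario = scenario,
    output_dir = output_dir,
    level = level,
    design = unclass(design_params()),
    localizer = list(n_runs = 2L),
    # named vectors are stored as named lists so the config survives a
    # JSON round trip (jsonlite drops names of atomic vectors)
    behavior = list(p_correct = list(veridical = 0.847, scrambled = 0.727),
                    p_no_response = 0.001, rt_shift_s = 0.3,
                    rt_meanlog = list(veridical = log(0.55),
                                      scrambled = log(0.75)),
                    rt_sdlog = 0.25),
    geometry = list(dim = c(20L, 20L, 10L), voxel_size_mm = c(3, 3, 4),
                    rois = list(ffa_like = list(center = c(6, 7, 4),
                                                n_voxels = 28L),
                                ofa_like = list(center = c(15, 14, 6),
                                                n_voxels = 32L))),
    ground_truth = list(stability_base = 0, stability_effect = 0.7,
                        pattern_mean = list(veridical = 1, scrambled = 0.93),
                        pattern_sd = 1, trial_noise_sd = 1,
                        localizer_amplitude = list(faces = 2, objects = 1,
                                                   houses = 1,
                                                   scrambled_objects = 0.8)),
    noise = unclass(noise_model()),
    hrf = unclass(hrf_params()),
    analysis = list(drift_order = 1L, define_rois = FALSE,
                    p_threshold = 0.01, min_size = 5L, connectivity = 26L,
                    localizer_fwhm_mm = 5, centering = TRUE,
                    fisher_z = FALSE, match_counts = TRUE,
                    alpha = 0.05, beta_noise_sd = 4.2),
    output = list(write_events = TRUE, write_bold = FALSE,
                  write_betas = TRUE, bold_format = "nifti"))
}

validate_keys <- function(cfg, template, path = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  unknown <- setdiff(names(cfg), names(template))
  # named-vector blocks (rois, p_correct, ...) allow free names
  free <- c("rois", "p_correct", "rt_meanlog", "pattern_mean",
            "localizer_amplitude")
  leaf <- basename(sub("/$", "", path))
  if (length(unknown) > 0 && !(leaf %in% free)) {
    stop(sprintf("unknown config key(s) at %s: %s", if (nzchar(path)) path
                 else "top level", paste(unknown, collapse = ", ")))
  }
  for (nm in intersect(names(cfg), names(template))) {
    if (is.list(template[[nm]])) {
      validate_keys(cfg[[nm]], template[[nm]], paste0(path, nm, "/"))
    }
  }
  invisible(TRUE)
}

# deep-merge user config over defaults (after key validation)
merge_config <- function(user, template) {
  if (!is.list(user)) return(user)
  out <- template
  for (nm in names(user)) {
    out[[nm]] <- if (is.list(template[[nm]]) && is.list(user[[nm]])) {
      merge_config(user[[nm]], template[[nm]])
    } else user[[nm]]
  }
  out
}

#' Load and validate a pipeline configuration
#'
#' @param config a config list, a path to a JSON config file, or NULL for
#'   defaults; partial configs are merged over [default_config].
#' @return the validated, completed configuration.
#' @export
load_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  template <- default_config()
  if (is.null(config)) return(template)
  validate_keys(config, template)
  cfg <- merge_config(config, template)
  for (nm in c("master_seed", "n_subjects", "n_runs")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  cfg
}

config_blocks <- function(cfg) {
  list(
    design_p = do.call(design_params, cfg$design),
    behavior_p = do.call(behavior_params, lapply(cfg$behavior, unlist)),
    geometry = geometry_params(cfg$geometry$dim, cfg$geometry$voxel_size_mm,
                               cfg$geometry$rois),
    noise = do.call(noise_model, cfg$noise),
    hrf_p = do.call(hrf_params, cfg$hrf),
    gt_args = lapply(cfg$ground_truth, unlist))
}

# 64-bit config fingerprint from two independent polynomial rolling hashes
config_fingerprint <- function(txt) {
  m <- 2147483647
  h1 <- 0; h2 <- 0
  for (b in utf8ToInt(txt)) {
    h1 <- (h1 * 131 + b) %% m
    h2 <- (h2 * 137 + b) %% m
  }
  sprintf("%08x%08x", h1, h2)
}

#' Localize ROIs for one subject from simulated localizer runs
#'
#' Simulates blocked localizer runs, fits the condition GLM with a
#' faces-vs-objects contrast on (optionally smoothed) data, and defines
#' one connected supra-threshold component per requested ROI, seeded at
#' the region's true center.  Regions that cannot be localized come back
#' empty (see [roi_is_empty]).
#'
#' @param ground_truth from [make_ground_truth].
#' @param seed integer seed.
#' @param n_runs number of localizer runs (default 2).
#' @param noise a [noise_model].
#' @param hrf_p an [hrf_params] list.
#' @param p_threshold,min_size,connectivity,fwhm_mm ROI-definition knobs.
#' @return named list of \code{roi_mask} objects.
#' @export
localize_rois <- function(ground_truth, seed, n_runs = 2,
                          noise = noise_model(), hrf_p = hrf_params(),
                          p_threshold = 0.01, min_size = 5L,
                          connectivity = 26, fwhm_mm = 5) {
  gt <- ground_truth
  runs <- lapply(seq_len(n_runs), function(r) {
    des <- generate_localizer_design(child_seed(seed, "locdesign"), r)
    bold <- simulate_localizer_run(des, gt, noise,
                                   child_seed(seed, "locrun", r), hrf_p)
    if (fwhm_mm > 0) {
      arr <- array(bold$data, c(gt$geometry$dim, ncol(bold$data)))
      for (k in seq_len(dim(arr)[4])) {
        arr[, , , k] <- smooth_volume(arr[, , , k], fwhm_mm,
                                      gt$geometry$voxel_size_mm)
      }
      bold$data <- matrix(arr, nrow(bold$data), ncol(bold$data))
    }
    list(des = des, bold = bold)
  })
  # one GLM over concatenated runs: shared condition columns, run-wise
  # drift and constant
  dms <- lapply(runs, function(r) {
    build_design_matrix(r$des, hrf_p, mode = "condition", drift_order = 1)
  })
  conds <- dms[[1]]$names[dms[[1]]$kind == "condition"]
  Xcond <- do.call(rbind, lapply(dms, function(dm) {
    dm$X[, dm$names %in% conds, drop = FALSE][, conds, drop = FALSE]
  }))
  nuis_blocks <- lapply(dms, function(dm) {
    dm$X[, dm$kind %in% c("drift", "constant"), drop = FALSE]
  })
  n_scans <- vapply(nuis_blocks, nrow, 1L)
  Xnuis <- matrix(0, sum(n_scans), sum(vapply(nuis_blocks, ncol, 1L)))
  row0 <- 0L; col0 <- 0L
  for (b in nuis_blocks) {
    Xnuis[row0 + seq_len(nrow(b)), col0 + seq_len(ncol(b))] <- b
    row0 <- row0 + nrow(b); col0 <- col0 + ncol(b)
  }
  X <- cbind(Xcond, Xnuis)
  colnames(X) <- c(conds, paste0("nuis_", seq_len(ncol(Xnuis))))
  dm_all <- structure(list(X = X, names = colnames(X),
                           kind = c(rep("condition", length(conds)),
                                    rep("drift", ncol(Xnuis))),
                           tr_s = dms[[1]]$tr_s, scan_times = NULL),
                      class = "design_matrix")
  Y <- do.call(rbind, lapply(runs, function(r) t(r$bold$data)))
  fit <- fit_glm(Y, dm_all, contrasts = list(
    faces_vs_objects = c(faces = 1, objects = -1)))
  tvol <- array(fit$contrast_t$faces_vs_objects, gt$geometry$dim)
  roi_names <- setdiff(names(gt$roi_masks), "background")
  masks <- lapply(roi_names, function(nm) {
    define_roi(tvol, fit$dof, p_threshold,
               component_seed = gt$geometry$rois[[nm]]$center,
               min_size = min_size, connectivity = connectivity, name = nm)
  })
  stats::setNames(masks, roi_names)
}

na_split_half <- function() {
  structure(data.frame(
    condition = rep(c("veridical", "scrambled"), each = 2),
    response = rep(c("correct", "incorrect"), 2),
    r = NA_real_, n_odd = 0L, n_even = 0L, flag = "empty_roi",
    stringsAsFactors = FALSE),
    class = c("split_half_result", "data.frame"))
}

na_mean_magnitude <- function() {
  data.frame(condition = rep(c("veridical", "scrambled"), each = 2),
             response = rep(c("correct", "incorrect"), 2),
             mean_amplitude = NA_real_, n_trials = 0L, flag = "empty_roi",
             stringsAsFactors = FALSE)
}

#' Run the full pipeline: simulate, estimate, correlate, infer
#'
#' Executes the whole chain for every subject under one configuration and
#' master seed, writes per-stage artifacts (BIDS-style events tables,
#' optional NIfTI volumes, trial-beta tables, a tidy split-half table, the
#' JSON and plain-text report) plus a manifest with the config hash, and
#' returns the compiled report.  A rerun with the same config is
#' bit-identical.
#'
#' @param config see [load_config].
#' @param write_artifacts write per-stage outputs (default TRUE).
#' @param verbose log per-subject progress.
#' @param inference compile and write the group report (default TRUE);
#'   FALSE stops after the per-subject stages (the \code{simulate} CLI
#'   subcommand), returning the cohort invisibly.
#' @return a \code{pattern_report} (invisibly the written paths as
#'   attribute \code{"paths"}).
#' @export
run_pipeline <- function(config = NULL, write_artifacts = TRUE,
                         verbose = FALSE, inference = TRUE) {
  cfg <- load_config(config)
  if (cfg$n_subjects < 2) {
    stop("inference requires n_subjects >= 2")
  }
  blocks <- config_blocks(cfg)
  out_dir <- cfg$output_dir
  if (write_artifacts) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  subjects <- paste0("sub", sprintf("%02d", seq_len(cfg$n_subjects)))
  analyses <- list(); matched <- list(); behaviors <- list()
  roi_names <- names(cfg$geometry$rois)
  a <- cfg$analysis

  for (subj in subjects) {
    t0 <- Sys.time()
    gt <- do.call(make_ground_truth,
                  c(list(scenario = cfg$scenario, geometry = blocks$geometry,
                         seed = child_seed(cfg$master_seed, subj, "gt")),
                    blocks$gt_args))
    masks <- gt$roi_masks[roi_names]
    if (isTRUE(a$define_rois) && cfg$level == "bold") {
      loc <- localize_rois(gt, child_seed(cfg$master_seed, subj, "loc"),
                           n_runs = cfg$localizer$n_runs,
                           noise = blocks$noise, hrf_p = blocks$hrf_p,
                           p_threshold = a$p_threshold,
                           min_size = a$min_size,
                           connectivity = a$connectivity,
                           fwhm_mm = a$localizer_fwhm_mm)
      masks <- lapply(loc, function(m) m$voxel_indices)
    }
    est_vox <- sort(unique(unlist(masks)))
    if (length(est_vox) < 2) {
      warning(sprintf("%s: no localizable ROI; subject excluded", subj))
      analyses[[subj]] <- stats::setNames(
        rep(list(list(split_half = na_split_half(),
                      mean_magnitude = na_mean_magnitude())),
            length(roi_names)), roi_names)
      next
    }
    sim <- tryCatch(
      simulate_subject(subj, cfg$master_seed, cfg$scenario, blocks$geometry,
                       cfg$n_runs, cfg$level, blocks$design_p,
                       blocks$behavior_p, blocks$noise, blocks$hrf_p,
                       blocks$gt_args, a$beta_noise_sd,
                       keep_raw = write_artifacts, mask = est_vox),
      error = function(e) {
        stop(sprintf("stage 'simulate/estimate' failed for %s: %s", subj,
                     conditionMessage(e)))
      })
    if (write_artifacts) {
      sdir <- file.path(out_dir, subj)
      dir.create(sdir, showWarnings = FALSE)
      for (r in seq_along(sim$runs)) {
        if (isTRUE(cfg$output$write_events)) {
          write_events_tsv(sim$runs[[r]]$design,
                           file.path(sdir, sprintf("run%02d_events.tsv", r)),
                           behavior = sim$runs[[r]]$beh)
        }
        if (isTRUE(cfg$output$write_bold) && cfg$level == "bold") {
          write_bold_nifti(sim$runs[[r]]$bold,
                           file.path(sdir, sprintf("run%02d_bold.nii.gz", r)))
        }
      }
      if (isTRUE(cfg$output$write_betas)) {
        write_trial_estimates_tsv(sim$trial_estimates,
                                  file.path(sdir, "trial_betas.tsv"))
      }
      jsonlite::write_json(
        lapply(masks, as.integer), file.path(sdir, "roi_masks.json"),
        auto_unbox = FALSE, digits = NA)
    }
    te <- tryCatch(suppressMessages(filter_trials(sim$trial_estimates)),
                   error = function(e) {
                     stop(sprintf("stage 'filter' failed for %s: %s", subj,
                                  conditionMessage(e)))
                   })
    one_roi <- function(te_use, vox) {
      if (length(vox) < 2) {
        return(list(split_half = na_split_half(),
                    mean_magnitude = na_mean_magnitude()))
      }
      rows <- roi_rows(te_use, vox)
      list(split_half = split_half_correlations(te_use, rows,
                                                centering = a$centering,
                                                fisher_z = a$fisher_z),
           mean_magnitude = roi_mean_magnitude(te_use, rows))
    }
    analyses[[subj]] <- lapply(masks, function(vox) one_roi(te, vox))
    if (isTRUE(a$match_counts)) {
      te_m <- suppressWarnings(
        match_trial_counts(te, child_seed(cfg$master_seed, subj)))
      matched[[subj]] <- lapply(masks, function(vox) one_roi(te_m, vox))
    }
    behaviors[[subj]] <- sim$behavior
    if (verbose) {
      message(sprintf("%s done in %.1f s", subj,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }

  cohort <- structure(list(analyses = analyses, matched = matched,
                           behaviors = behaviors, rois = roi_names,
                           scenario = cfg$scenario, n_runs = cfg$n_runs,
                           level = cfg$level,
                           master_seed = cfg$master_seed),
                      class = "cohort_result")
  if (!inference) return(invisible(cohort))
  report <- compile_report(cohort, alpha = a$alpha)
  paths <- character(0)
  if (write_artifacts) {
    tidy <- tidy_split_half(lapply(analyses, function(x) {
      lapply(x, `[[`, "split_half")
    }))
    write_split_half_tsv(tidy, file.path(out_dir, "split_half.tsv"))
    write_report(report, file.path(out_dir, "report.json"))
    writeLines(render_report_text(report), file.path(out_dir, "report.txt"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("patternsplit")),
      master_seed = cfg$master_seed,
      config = cfg,
      config_hash = config_fingerprint(as.character(jsonlite::toJSON(
        cfg, auto_unbox = TRUE, digits = NA))),
      subject_seeds = stats::setNames(
        lapply(subjects, function(s) child_seed(cfg$master_seed, s)),
        subjects))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- file.path(out_dir, c("split_half.tsv", "report.json",
                                  "report.txt", "manifest.json"))
  }
  attr(report, "paths") <- paths
  report
}

#' Write / read a trial-estimate table as tab-separated text
#'
#' Long format: one row per voxel x trial would be huge, so the matrix is
#' stored wide — metadata columns (trial_id, run_id, condition, response)
#' followed by one column per voxel (named \code{v<grid index>}).
#'
#' @param trial_estimates a \code{trial_estimates}.
#' @param path output path.
#' @export
write_trial_estimates_tsv <- function(trial_estimates, path) {
  te <- trial_estimates
  amp <- t(te$amplitudes)
  colnames(amp) <- paste0("v", te$voxel_indices)
  df <- cbind(te$meta, as.data.frame(amp))
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_estimates_tsv
#' @export
read_trial_estimates_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  vcol <- grep("^v[0-9]+$", names(df))
  amp <- t(as.matrix(df[, vcol, drop = FALSE]))
  new_trial_estimates(amp, df[, setdiff(names(df), names(df)[vcol]),
                              drop = FALSE],
                      voxel_indices = as.integer(sub("^v", "",
                                                     names(df)[vcol])))
}
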