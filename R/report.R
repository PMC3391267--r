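anova_effect_list <- function(x) {
  list(name = x$name, F = x$F, df1 = x$df1, df2 = x$df2, p = x$p,
       partial_eta_sq = x$partial_eta_sq, n = x$n, mean_score = x$mean_score)
}

t_test_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(t = x$t, df = x$df, p = x$p, d = x$d, n = x$n,
       mean_diff = x$mean_diff, degenerate = isTRUE(x$degenerate))
}

#' Group-level 2x2 inference for one ROI's cell table
#'
#' Runs the three 1-df within-subject effects (condition, response,
#' interaction) on the subjects x cells table and the two post-hoc paired
#' t tests (correct vs incorrect within each condition).  Subjects with
#' any undefined cell are dropped listwise; reported dfs reflect that.
#'
#' @param cell_table subjects x 4 matrix (see [cohort_cell_table]).
#' @return list of \code{anova_effect}s and \code{t_test_result}s.
#' @export
roi_inference_2x2 <- function(cell_table) {
  cw <- contrasts_2x2()
  complete <- rowSums(is.na(cell_table)) == 0
  y <- cell_table[complete, , drop = FALSE]
  effects <- lapply(names(cw), function(nm) {
    rm_anova_1df(y, cw[[nm]], name = nm)
  })
  names(effects) <- names(cw)
  posthoc <- list(
    veridical = paired_t(y[, "veridical.correct"], y[, "veridical.incorrect"]),
    scrambled = paired_t(y[, "scrambled.correct"], y[, "scrambled.incorrect"]))
  list(effects = effects, posthoc = posthoc, n_subjects = nrow(y))
}

#' Scenario verdict from an ROI's 2x2 inference
#'
#' Decides which representational scheme the data support at level
#' \code{alpha}: a significant condition-by-response interaction with a
#' significant correct-over-incorrect advantage for veridical faces only
#' is \code{"holistic"}; with the advantage in both conditions,
#' \code{"both"}; a significant response main effect without interaction
#' is \code{"parts_based"}; nothing significant is \code{"null"};
#' anything else is \code{"indeterminate"}.
#'
#' @param inference output of [roi_inference_2x2].
#' @param alpha significance level (default 0.05).
#' @return one of the scenario labels or \code{"indeterminate"}.
#' @export
scenario_verdict <- function(inference, alpha = 0.05) {
  eff <- inference$effects
  ph <- inference$posthoc
  sig <- function(x) !is.null(x) && !isTRUE(x$degenerate) &&
    !is.na(x$p) && x$p < alpha
  adv <- function(x) sig(x) && x$mean_diff > 0
  if (sig(eff$interaction)) {
    if (adv(ph$veridical) && !adv(ph$scrambled)) return("holistic")
    if (adv(ph$veridical) && adv(ph$scrambled)) return("both")
    return("indeterminate")
  }
  if (adv(ph$veridical) && adv(ph$scrambled) || sig(eff$response)) {
    return("parts_based")
  }
  "null"
}

#' Compile the full group report for a cohort
#'
#' Gathers the behavioral summary, per-ROI split-half correlation tables
#' with their 2x2 ANOVA effects and post-hoc tests, the matched-trial
#' control (when the cohort carries it), the mean-magnitude control
#' (the same 2x2 on pooled ROI amplitudes), the region x response and
#' three-way effects across the first two ROIs when present, and the
#' scenario verdict from the primary (first) ROI.
#'
#' @param cohort a \code{cohort_result} from [simulate_cohort].
#' @param alpha significance level for the verdict.
#' @return a \code{pattern_report} (nested list, JSON-serializable via
#'   [write_report]).
#' @export
compile_report <- function(cohort, alpha = 0.05) {
  behav <- behavioral_summary(cohort$behaviors)
  rois <- cohort$rois
  roi_reports <- lapply(rois, function(nm) {
    tab <- cohort_cell_table(cohort, nm)
    inf <- roi_inference_2x2(tab)
    mag_tab <- cohort_magnitude_table(cohort, nm)
    mag_inf <- roi_inference_2x2(mag_tab)
    out <- list(
      cell_means = colMeans(tab, na.rm = TRUE),
      cell_table = tab,
      effects = lapply(inf$effects, anova_effect_list),
      posthoc = lapply(inf$posthoc, t_test_list),
      n_subjects = inf$n_subjects,
      mean_magnitude = list(cell_means = colMeans(mag_tab, na.rm = TRUE),
                            effects = lapply(mag_inf$effects,
                                             anova_effect_list)))
    if (length(cohort$matched) > 0) {
      mtab <- cohort_cell_table(cohort, nm, matched = TRUE)
      minf <- roi_inference_2x2(mtab)
      out$matched <- list(cell_means = colMeans(mtab, na.rm = TRUE),
                          effects = lapply(minf$effects, anova_effect_list),
                          posthoc = lapply(minf$posthoc, t_test_list))
    }
    out
  })
  names(roi_reports) <- rois

  cross_roi <- NULL
  if (length(rois) >= 2) {
    t1 <- cohort_cell_table(cohort, rois[1])
    t2 <- cohort_cell_table(cohort, rois[2])
    colnames(t1) <- paste(rois[1], colnames(t1), sep = ".")
    colnames(t2) <- paste(rois[2], colnames(t2), sep = ".")
    y8 <- cbind(t1, t2)
    resp_sign <- ifelse(grepl("\\.correct$", colnames(y8)), 1, -1)
    cond_sign <- ifelse(grepl("veridical", colnames(y8)), 1, -1)
    region_sign <- ifelse(grepl(paste0("^", rois[1]), colnames(y8)), 1, -1)
    three_way <- rm_anova_1df(y8, resp_sign * cond_sign * region_sign,
                              name = "region_x_condition_x_response")
    scr <- grepl("scrambled", colnames(y8))
    rxr_scr <- rm_anova_1df(y8[, scr, drop = FALSE],
                            (resp_sign * region_sign)[scr],
                            name = "region_x_response_scrambled")
    cross_roi <- list(three_way = anova_effect_list(three_way),
                      region_x_response_scrambled = anova_effect_list(rxr_scr))
  }

  primary <- roi_inference_2x2(cohort_cell_table(cohort, rois[1]))
  structure(list(
    scenario = cohort$scenario,
    n_subjects = length(cohort$analyses),
    n_runs = cohort$n_runs,
    level = cohort$level,
    alpha = alpha,
    behavioral = list(
      group_means = behav$group_means,
      accuracy_test = t_test_list(behav$accuracy_test),
      rt_test = t_test_list(behav$rt_test)),
    rois = roi_reports,
    cross_roi = cross_roi,
    verdict = scenario_verdict(primary, alpha)),
    class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(render_report_text(x), sep = "\n")
  invisible(x)
}

#' Plain-text rendering of a report
#' @param report a \code{pattern_report}.
#' @return character vector of lines.
#' @export
render_report_text <- function(report) {
  fmt_eff <- function(e) {
    sprintf("  %s: F(%d,%d) = %.2f, p = %.4f, partial eta^2 = %.2f",
            e$name, e$df1, e$df2, e$F, e$p, e$partial_eta_sq)
  }
  fmt_t <- function(nm, tt) {
    if (is.null(tt)) return(sprintf("  %s: (not computed)", nm))
    if (isTRUE(tt$degenerate)) return(sprintf("  %s: degenerate", nm))
    sprintf("  %s: t(%d) = %.2f, p = %.4f, d = %.2f", nm, tt$df, tt$t, tt$p,
            tt$d)
  }
  out <- c(
    sprintf("Split-half pattern analysis report (scenario: %s, %d subjects, %d runs)",
            report$scenario, report$n_subjects, report$n_runs),
    "Behavior (accuracy / RT by condition):",
    utils::capture.output(print(report$behavioral$group_means)),
    fmt_t("accuracy veridical vs scrambled", report$behavioral$accuracy_test),
    fmt_t("RT veridical vs scrambled", report$behavioral$rt_test))
  for (nm in names(report$rois)) {
    r <- report$rois[[nm]]
    out <- c(out, sprintf("ROI %s (n = %d): split-half correlations %s", nm,
                          r$n_subjects,
                          paste(sprintf("%s=%.3f", names(r$cell_means),
                                        r$cell_means), collapse = ", ")),
             vapply(r$effects, fmt_eff, ""),
             fmt_t("veridical correct vs incorrect", r$posthoc$veridical),
             fmt_t("scrambled correct vs incorrect", r$posthoc$scrambled))
  }
  if (!is.null(report$cross_roi)) {
    out <- c(out, "Cross-ROI effects:",
             fmt_eff(report$cross_roi$region_x_response_scrambled),
             fmt_eff(report$cross_roi$three_way))
  }
  c(out, sprintf("Verdict at alpha = %.2f: %s", report$alpha, report$verdict))
}

report_to_list <- function(report) {
  x <- unclass(report)
  x$behavioral$group_means <- as.list(x$behavioral$group_means)
  for (nm in names(x$rois)) {
    x$rois[[nm]]$cell_means <- as.list(x$rois[[nm]]$cell_means)
    tab <- x$rois[[nm]]$cell_table
    x$rois[[nm]]$cell_table <- c(list(subject = rownames(tab)),
                                 as.list(as.data.frame(tab)))
    x$rois[[nm]]$mean_magnitude$cell_means <-
      as.list(x$rois[[nm]]$mean_magnitude$cell_means)
    if (!is.null(x$rois[[nm]]$matched)) {
      x$rois[[nm]]$matched$cell_means <-
        as.list(x$rois[[nm]]$matched$cell_means)
    }
  }
  x
}

#' Write / read a report as JSON
#'
#' The JSON schema is stable: scenario, n_subjects, n_runs, level, alpha,
#' behavioral, rois (each with cell means, per-subject cell table, ANOVA
#' effects, post-hocs, mean-magnitude control, optional matched control),
#' cross_roi, verdict.  \code{read_report} round-trips losslessly from
#' [write_report] output.
#'
#' @param report a \code{pattern_report}.
#' @param path output (.json) path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
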