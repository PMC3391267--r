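test_that("cohort simulation is deterministic per master seed", {
  geom <- reduced_geometry()
  c1 <- simulate_cohort(n_subjects = 3, scenario = "holistic",
                        master_seed = 5, geometry = geom, n_runs = 2,
                        level = "amplitude")
  c2 <- simulate_cohort(n_subjects = 3, scenario = "holistic",
                        master_seed = 5, geometry = geom, n_runs = 2,
                        level = "amplitude")
  expect_identical(cohort_cell_table(c1, "ffa_like"),
                   cohort_cell_table(c2, "ffa_like"))
  c3 <- simulate_cohort(n_subjects = 3, scenario = "holistic",
                        master_seed = 6, geometry = geom, n_runs = 2,
                        level = "amplitude")
  expect_false(identical(cohort_cell_table(c1, "ffa_like"),
                         cohort_cell_table(c3, "ffa_like")))
})

test_that("holistic cohorts show the veridical-only reliability advantage", {
  st <- calibration_study(30, "holistic", master_seed = 77)
  ver_diff <- mean(st$r_veridical_correct - st$r_veridical_incorrect)
  scr_diff <- mean(st$r_scrambled_correct - st$r_scrambled_incorrect)
  expect_gt(ver_diff, 0.2)
  expect_lt(abs(scr_diff), 0.4 * ver_diff)
})

test_that("null cohorts have four equal group-mean correlations", {
  st <- calibration_study(60, "null", master_seed = 78)
  means <- colMeans(st[, c("r_veridical_correct", "r_veridical_incorrect",
                           "r_scrambled_correct", "r_scrambled_incorrect")])
  # all near zero and near each other, within Monte-Carlo error
  expect_lt(max(abs(means)), 0.03)
  expect_lt(diff(range(means)), 0.05)
})

test_that("amplitude and bold levels agree on the group-level statistics", {
  geom <- reduced_geometry()
  cb <- simulate_cohort(n_subjects = 6, scenario = "holistic",
                        master_seed = 9, geometry = geom, n_runs = 4,
                        level = "bold")
  ca <- simulate_cohort(n_subjects = 6, scenario = "holistic",
                        master_seed = 9, geometry = geom, n_runs = 4,
                        level = "amplitude")
  tb <- cohort_cell_table(cb, "ffa_like")
  ta <- cohort_cell_table(ca, "ffa_like")
  # same qualitative structure: strong veridical-correct reliability,
  # weak elsewhere, comparable magnitudes across simulation levels
  expect_gt(mean(tb[, "veridical.correct"]), 0.25)
  expect_lt(abs(mean(tb[, "veridical.correct"]) -
                  mean(ta[, "veridical.correct"])), 0.2)
  expect_lt(abs(mean(tb[, "scrambled.incorrect"]) -
                  mean(ta[, "scrambled.incorrect"])), 0.2)
})

test_that("reports carry the full inference and round-trip through JSON", {
  geom <- reduced_geometry()
  cohort <- simulate_cohort(n_subjects = 5, scenario = "holistic",
                            master_seed = 10, geometry = geom, n_runs = 4,
                            level = "amplitude", match_counts = TRUE)
  rep <- compile_report(cohort)
  expect_s3_class(rep, "pattern_report")
  expect_named(rep$rois, "ffa_like")
  expect_named(rep$rois$ffa_like$effects,
               c("condition", "response", "interaction"))
  expect_true(!is.null(rep$rois$ffa_like$matched))
  expect_true(rep$verdict %in% c("holistic", "parts_based", "both", "null",
                                 "indeterminate"))
  txt <- render_report_text(rep)
  expect_true(any(grepl("Verdict", txt)))

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$verdict, rep$verdict)
  expect_equal(back$rois$ffa_like$effects$interaction$F,
               rep$rois$ffa_like$effects$interaction$F, tolerance = 1e-12)
  # lossless round trip of the serialized form
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(back, path2, auto_unbox = TRUE, digits = NA,
                       null = "null")
  expect_equal(jsonlite::read_json(path2, simplifyVector = TRUE), back)
})

test_that("cross-ROI effects appear when two ROIs are analyzed", {
  cohort <- simulate_cohort(n_subjects = 5, scenario = "holistic",
                            master_seed = 12, n_runs = 4,
                            level = "amplitude")
  rep <- compile_report(cohort)
  expect_named(rep$rois, c("ffa_like", "ofa_like"))
  expect_false(is.null(rep$cross_roi))
  expect_equal(rep$cross_roi$three_way$df1, 1L)
  expect_equal(rep$cross_roi$three_way$df2, 4L)
})

test_that("scenario verdicts follow the decision rule", {
  mk <- function(p_int, p_resp, p_ver, p_scr, d_ver = 1, d_scr = 1) {
    list(effects = list(
      condition = list(p = 0.5, degenerate = FALSE),
      response = list(p = p_resp, degenerate = FALSE),
      interaction = list(p = p_int, degenerate = FALSE)),
      posthoc = list(
        veridical = list(p = p_ver, mean_diff = d_ver, degenerate = FALSE),
        scrambled = list(p = p_scr, mean_diff = d_scr, degenerate = FALSE)))
  }
  expect_equal(scenario_verdict(mk(0.01, 0.5, 0.01, 0.5)), "holistic")
  expect_equal(scenario_verdict(mk(0.01, 0.01, 0.01, 0.01)), "both")
  expect_equal(scenario_verdict(mk(0.5, 0.01, 0.01, 0.01)), "parts_based")
  expect_equal(scenario_verdict(mk(0.5, 0.5, 0.5, 0.5)), "null")
  # significant interaction but no interpretable post-hoc pattern
  expect_equal(scenario_verdict(mk(0.01, 0.5, 0.5, 0.5)), "indeterminate")
})
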