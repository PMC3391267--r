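test_that("default experimental design reproduces the run timing", {
  d <- generate_experimental_design(1, seed = 7)
  expect_equal(design_span(d), 328)
  expect_equal(d$n_scans, 164L)
  ev <- d$events
  expect_equal(sum(ev$condition == "veridical"), 36)
  expect_equal(sum(ev$condition == "scrambled"), 36)
  expect_equal(sum(ev$condition == "fixation"), 12)
  expect_true(all(ev$duration[ev$condition != "fixation"] == 4))
  expect_true(all(ev$duration[ev$condition == "fixation"] == 2))
  # lead-in and lead-out of 8 s
  expect_equal(min(ev$onset), 8)
  expect_equal(max(ev$onset + ev$duration), 320)
})

test_that("event designs satisfy ordering, non-overlap and span accounting", {
  for (seed in 1:5) {
    p <- design_params(n_veridical = sample(5:40, 1),
                       n_scrambled = sample(5:40, 1),
                       n_fixation = sample(0:12, 1))
    d <- generate_experimental_design(2, seed, p)
    ev <- d$events
    expect_true(all(diff(ev$onset) > 0))
    expect_true(all(ev$onset[-1] >= (ev$onset + ev$duration)[-nrow(ev)]))
    expect_true(all(ev$onset >= 0))
    expect_equal(design_span(d),
                 sum(ev$duration) + p$lead_in_s + p$lead_out_s)
  }
})

test_that("designs are deterministic per (run_id, seed) and vary otherwise", {
  a <- generate_experimental_design(3, 11)
  b <- generate_experimental_design(3, 11)
  c <- generate_experimental_design(4, 11)
  d <- generate_experimental_design(3, 12)
  expect_identical(a, b)
  expect_false(identical(a$events$condition, c$events$condition))
  expect_false(identical(a$events$condition, d$events$condition))
})

test_that("degenerate and invalid design parameters are handled", {
  empty <- generate_experimental_design(
    1, 1, design_params(n_veridical = 0, n_scrambled = 0, n_fixation = 0,
                        lead_in_s = 0, lead_out_s = 0))
  expect_equal(design_span(empty), 0)
  expect_equal(nrow(empty$events), 0)
  expect_error(
    generate_experimental_design(1, 1, design_params(lead_in_s = 7)),
    "multiple")
})

test_that("localizer design has the blocked structure and 336-s span", {
  d <- generate_localizer_design(seed = 5)
  expect_equal(design_span(d), 336)
  ev <- d$events
  expect_equal(sum(ev$condition == "fixation"), 5)
  expect_equal(sum(ev$condition != "fixation"), 16)
  expect_true(all(ev$duration == 16))
  # each category once per quarter
  blocks <- ev$condition[ev$condition != "fixation"]
  for (q in 1:4) {
    expect_setequal(blocks[(q - 1) * 4 + 1:4],
                    c("faces", "objects", "houses", "scrambled_objects"))
  }
  # within-block stimulus accounting: 20 x (0.3 + 0.5) s fills 16 s
  p <- localizer_params()
  expect_equal(p$stims_per_block * (p$stim_on_s + p$stim_off_s),
               p$block_duration_s)
  expect_identical(d, generate_localizer_design(seed = 5))
  expect_error(generate_localizer_design(1, params = localizer_params(
    stims_per_block = 19)), "block")
})

test_that("transition-count diagnostic sums to events minus one", {
  d <- generate_experimental_design(1, 3)
  tc <- transition_counts(d)
  expect_equal(sum(tc), nrow(d$events) - 1)
  expect_equal(rownames(tc), c("fixation", "scrambled", "veridical"))
})

test_that("events round-trip through the BIDS-style TSV", {
  d <- generate_experimental_design(2, 9)
  b <- simulate_behavior(d, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(d, path, behavior = b)
  back <- read_events_tsv(path)
  expect_equal(back$design$events, d$events)
  expect_equal(back$design$n_scans, d$n_scans)
  expect_equal(back$design$tr_s, d$tr_s)
  expect_equal(back$behavior$response, b$response)
  expect_equal(back$behavior$rt_s, b$rt_s)
})
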