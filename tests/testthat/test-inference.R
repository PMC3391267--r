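test_that("paired t matches the textbook computation and stats::t.test", {
  a <- c(1, 2, 3, 4); b <- c(0, 2, 2, 5)
  res <- paired_t(a, b)
  oracle <- paired_t_oracle(a, b)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$d, oracle$d, tolerance = 1e-12)
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter))
})

test_that("paired t is antisymmetric and degenerates cleanly", {
  set.seed(1)
  a <- rnorm(9); b <- rnorm(9)
  r1 <- paired_t(a, b); r2 <- paired_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$d, -r2$d)
  expect_equal(r1$p, r2$p)
  same <- paired_t(a, a)
  expect_true(same$degenerate)
  # identical nonzero shift: sd(diff) = 0
  shift <- paired_t(c(2, 3, 4, 7), c(1, 2, 3, 6))
  expect_true(shift$degenerate)
  # missing pairs deleted pairwise
  a[3] <- NA
  expect_equal(paired_t(a, b)$n, 8)
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("partial eta squared follows F*df1/(F*df1+df2)", {
  expect_equal(partial_eta_sq(0, 1, 12), 0)
  expect_equal(partial_eta_sq(5, 1, 5), 0.5)
  # strictly increasing in F, decreasing in df2
  fs <- seq(0.1, 20, length.out = 30)
  expect_true(all(diff(partial_eta_sq(fs, 1, 12)) > 0))
  dfs <- 2:30
  expect_true(all(diff(vapply(dfs, function(d) partial_eta_sq(4, 1, d),
                              0)) < 0))
})

test_that("1-df within-subject effects match the sums-of-squares ANOVA", {
  cw <- contrasts_2x2()
  for (seed in 1:6) {
    set.seed(seed)
    tab <- matrix(rnorm(24, mean = 2), 6, 4,
                  dimnames = list(NULL, patternsplit:::cell_names))
    oracle <- rm_anova_oracle_2x2(tab)
    for (nm in names(cw)) {
      eff <- rm_anova_1df(tab, cw[[nm]], name = nm)
      expect_equal(eff$F, unname(oracle[nm]), tolerance = 1e-8)
      expect_equal(eff$df2, 5L)
    }
  }
})

test_that("the 1-df F is the square of the contrast-score paired t", {
  set.seed(2)
  tab <- matrix(rnorm(32), 8, 4,
                dimnames = list(NULL, patternsplit:::cell_names))
  w <- contrasts_2x2()$interaction
  eff <- rm_anova_1df(tab, w)
  score <- drop(tab %*% patternsplit:::normalize_contrast(w))
  tt <- paired_t(score, rep(0, 8))
  expect_equal(eff$F, tt$t^2, tolerance = 1e-10)
  expect_equal(eff$partial_eta_sq,
               eff$F / (eff$F + eff$df2), tolerance = 1e-12)
})

test_that("rm_anova_1df is exchangeable over subjects and handles missing", {
  set.seed(3)
  tab <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, patternsplit:::cell_names))
  w <- contrasts_2x2()$response
  f1 <- rm_anova_1df(tab, w)$F
  f2 <- rm_anova_1df(tab[sample(10), ], w)$F
  expect_equal(f1, f2, tolerance = 1e-12)
  tab[c(2, 5), 3] <- NA
  eff <- rm_anova_1df(tab, w)
  expect_equal(eff$n, 8)
  expect_equal(eff$df2, 7L)
  # identical rows across subjects: zero-variance contrast, F = 0
  same <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4,
                 dimnames = list(NULL, patternsplit:::cell_names))
  expect_equal(rm_anova_1df(same, contrasts_2x2()$interaction)$F, 0)
  expect_error(rm_anova_1df(tab[1, , drop = FALSE], w), "2 subjects")
})

test_that("behavioral summary aggregates accuracy and correct-trial RT", {
  d1 <- generate_experimental_design(1, 1)
  behs <- lapply(1:4, function(s) {
    do.call(rbind, lapply(1:2, function(r) {
      simulate_behavior(generate_experimental_design(r, s), seed = s)
    }))
  })
  names(behs) <- paste0("sub", 1:4)
  bs <- behavioral_summary(behs)
  expect_equal(nrow(bs$per_subject), 8)
  expect_true(all(bs$per_subject$accuracy >= 0 & bs$per_subject$accuracy <= 1))
  expect_s3_class(bs$accuracy_test, "t_test_result")
  # RT over correct trials only differs from all-trials RT
  bs_all <- behavioral_summary(behs, rt_correct_only = FALSE)
  expect_false(isTRUE(all.equal(bs$per_subject$mean_rt_s,
                                bs_all$per_subject$mean_rt_s)))
  expect_error(behavioral_summary(behs[1]), "2 subjects")
})

test_that("all-correct behavior degenerates the accuracy test", {
  p <- behavior_params(p_correct = c(veridical = 1, scrambled = 1),
                       p_no_response = 0)
  behs <- lapply(1:3, function(s) {
    simulate_behavior(generate_experimental_design(1, s), p, seed = s)
  })
  names(behs) <- paste0("sub", 1:3)
  bs <- behavioral_summary(behs)
  expect_true(all(bs$per_subject$accuracy == 1))
  expect_true(bs$accuracy_test$degenerate)
})
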