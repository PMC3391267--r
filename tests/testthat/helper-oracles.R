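# Independent oracles, deliberately written with explicit loops and
# textbook formulas so they share no code with the implementation.

CELLS <- c("veridical.correct", "veridical.incorrect",
           "scrambled.correct", "scrambled.incorrect")

# Brute-force behavior-sorted split-half correlations: loops over voxels
# and trials, no matrix algebra.
split_half_oracle <- function(amp, meta) {
  n_vox <- nrow(amp)
  half_of <- function(run) if (run %% 2 == 1) "odd" else "even"
  cell_of <- function(i) paste(meta$condition[i], meta$response[i], sep = ".")
  cell_mean <- function(half, cell) {
    out <- numeric(n_vox)
    for (v in seq_len(n_vox)) {
      tot <- 0; n <- 0
      for (i in seq_len(ncol(amp))) {
        if (half_of(meta$run_id[i]) == half && cell_of(i) == cell) {
          tot <- tot + amp[v, i]; n <- n + 1
        }
      }
      out[v] <- tot / n
    }
    out
  }
  centered <- function(half) {
    m <- list()
    for (cl in CELLS) m[[cl]] <- cell_mean(half, cl)
    for (v in seq_len(n_vox)) {
      vm <- 0
      for (cl in CELLS) vm <- vm + m[[cl]][v]
      vm <- vm / length(CELLS)
      for (cl in CELLS) m[[cl]][v] <- m[[cl]][v] - vm
    }
    m
  }
  odd <- centered("odd"); even <- centered("even")
  pearson <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    sxy <- 0; sxx <- 0; syy <- 0
    for (v in seq_len(n)) {
      sxy <- sxy + (x[v] - mx) * (y[v] - my)
      sxx <- sxx + (x[v] - mx)^2
      syy <- syy + (y[v] - my)^2
    }
    sxy / sqrt(sxx * syy)
  }
  r <- numeric(length(CELLS)); names(r) <- CELLS
  for (cl in CELLS) r[cl] <- pearson(odd[[cl]], even[[cl]])
  r
}

# random small trial-estimate instance with every cell present in both
# halves (n_runs even, runs alternate odd/even)
random_instance <- function(n_vox = 5, trials_per_cell_per_run = 2,
                            n_runs = 2) {
  meta <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    expand.grid(condition = c("veridical", "scrambled"),
                response = c("correct", "incorrect"),
                rep = seq_len(trials_per_cell_per_run),
                stringsAsFactors = FALSE)[, 1:2] |>
      transform(run_id = r)
  }))
  meta$trial_id <- seq_len(nrow(meta))
  amp <- matrix(rnorm(n_vox * nrow(meta)), n_vox, nrow(meta))
  list(amp = amp, meta = meta)
}

# Full sums-of-squares repeated-measures ANOVA via stats::aov with an
# Error(subject/(A*B)) stratum decomposition.
rm_anova_oracle_2x2 <- function(tab) {
  n <- nrow(tab)
  long <- data.frame(
    y = as.vector(tab),
    subj = factor(rep(seq_len(n), times = 4)),
    cond = factor(rep(c("veridical", "veridical", "scrambled", "scrambled"),
                      each = n)),
    resp = factor(rep(c("correct", "incorrect", "correct", "incorrect"),
                      each = n)))
  fit <- stats::aov(y ~ cond * resp + Error(subj / (cond * resp)),
                    data = long)
  s <- summary(fit)
  grab <- function(stratum, term) {
    tb <- s[[stratum]][[1]]
    tb[trimws(rownames(tb)) == term, "F value"]
  }
  c(condition = grab("Error: subj:cond", "cond"),
    response = grab("Error: subj:resp", "resp"),
    interaction = grab("Error: subj:cond:resp", "cond:resp"))
}

# textbook paired t: explicit mean/sd of differences
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tval <- m / (s / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), n - 1), d = m / s)
}

quiet_filter <- function(te) suppressMessages(patternsplit::filter_trials(te))
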