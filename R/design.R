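#' Parameters of the event-related experimental design
#'
#' Defaults reproduce the study design the generator emulates: per run,
#' 36 veridical-face and 36 scrambled-face trials of 4 s each, twelve 2-s
#' fixation trials interleaved as temporal jitter, an 8-s fixation lead-in
#' and lead-out, and a repetition time of 2 s, giving a 328-s run.
#'
#' @param n_veridical,n_scrambled number of face-pair trials per condition.
#' @param trial_duration_s duration of one face-pair trial, seconds.
#' @param n_fixation number of jitter fixation trials.
#' @param fixation_duration_s duration of one fixation trial, seconds.
#' @param lead_in_s,lead_out_s fixation padding at run start/end, seconds.
#' @param tr_s repetition time, seconds.
#' @return a list of class \code{design_params}.
#' @export
design_params <- function(n_veridical = 36, n_scrambled = 36,
                          trial_duration_s = 4,
                          n_fixation = 12, fixation_duration_s = 2,
                          lead_in_s = 8, lead_out_s = 8, tr_s = 2) {
  p <- list(n_veridical = n_veridical, n_scrambled = n_scrambled,
            trial_duration_s = trial_duration_s,
            n_fixation = n_fixation, fixation_duration_s = fixation_duration_s,
            lead_in_s = lead_in_s, lead_out_s = lead_out_s, tr_s = tr_s)
  class(p) <- "design_params"
  p
}

new_event_design <- function(events, run_id, tr_s, n_scans) {
  stopifnot(is.data.frame(events))
  d <- list(events = events, run_id = run_id, tr_s = tr_s, n_scans = n_scans)
  class(d) <- "event_design"
  d
}

#' @export
print.event_design <- function(x, ...) {
  cat(sprintf("<event_design> run %s: %d events, %d scans, TR %g s, span %g s\n",
              x$run_id, nrow(x$events), x$n_scans, x$tr_s, design_span(x)))
  invisible(x)
}

#' Total temporal span of a design in seconds
#'
#' Span is lead-in + summed event durations + lead-out, and always equals
#' \code{n_scans * tr_s}.
#'
#' @param design an \code{event_design}.
#' @return span in seconds.
#' @export
design_span <- function(design) design$n_scans * design$tr_s

#' Generate one event-related experimental run
#'
#' Trials (veridical, scrambled, fixation jitters) are interleaved by a
#' seeded random permutation; onsets fill the run back-to-back after the
#' lead-in.  Counterbalancing is therefore stochastic rather than optimized;
#' use [transition_counts] to inspect the realized first-order transition
#' structure of a design.
#'
#' Trial ids are assigned to non-fixation trials in presentation order and
#' are globally unique across runs (offset by \code{run_id}).
#'
#' @param run_id 1-based run index.
#' @param seed integer seed; the design is a deterministic function of
#'   \code{(run_id, seed)}.
#' @param params a [design_params] list.
#' @return an \code{event_design}: events (onset, duration, condition,
#'   trial_id), run id, TR, scan count.
#' @examples
#' d <- generate_experimental_design(1, seed = 1)
#' design_span(d)  # 328
#' @export
generate_experimental_design <- function(run_id, seed, params = design_params()) {
  p <- params
  durs <- c(rep(p$trial_duration_s, p$n_veridical + p$n_scrambled),
            rep(p$fixation_duration_s, p$n_fixation))
  conds <- c(rep("veridical", p$n_veridical), rep("scrambled", p$n_scrambled),
             rep("fixation", p$n_fixation))
  span <- p$lead_in_s + sum(durs) + p$lead_out_s
  if (span %% p$tr_s != 0) {
    stop(sprintf("run span %g s is not a multiple of tr_s = %g s", span, p$tr_s))
  }
  n <- length(durs)
  ord <- if (n > 0) with_seed(child_seed(seed, "design", run_id), sample.int(n)) else integer(0)
  durs <- durs[ord]; conds <- conds[ord]
  onsets <- p$lead_in_s + cumsum(c(0, durs))[seq_len(n)]
  n_stim <- p$n_veridical + p$n_scrambled
  trial_id <- rep(NA_integer_, n)
  trial_id[conds != "fixation"] <- (run_id - 1L) * n_stim + seq_len(sum(conds != "fixation"))
  events <- data.frame(onset = onsets, duration = durs, condition = conds,
                       trial_id = trial_id, stringsAsFactors = FALSE)
  new_event_design(events, run_id, p$tr_s, as.integer(span / p$tr_s))
}

#' Parameters of the blocked localizer design
#'
#' Defaults emulate the localizer the generator mimics: sixteen 16-s
#' category blocks (4 categories x 4 blocks) with five 16-s fixation
#' periods interleaved (one before each quarter and one at the end),
#' a 336-s run.  Within a block, 20 stimuli at 300 ms on + 500 ms off
#' account exactly for the 16 s.
#'
#' @param categories stimulus category labels.
#' @param blocks_per_category blocks per category per run.
#' @param block_duration_s block length, seconds.
#' @param n_fixation number of fixation periods.
#' @param fixation_duration_s fixation period length, seconds.
#' @param stims_per_block,stim_on_s,stim_off_s within-block stimulus timing.
#' @param tr_s repetition time, seconds.
#' @export
localizer_params <- function(categories = c("faces", "objects", "houses",
                                            "scrambled_objects"),
                             blocks_per_category = 4,
                             block_duration_s = 16,
                             n_fixation = 5, fixation_duration_s = 16,
                             stims_per_block = 20, stim_on_s = 0.3,
                             stim_off_s = 0.5, tr_s = 2) {
  p <- list(categories = categories, blocks_per_category = blocks_per_category,
            block_duration_s = block_duration_s, n_fixation = n_fixation,
            fixation_duration_s = fixation_duration_s,
            stims_per_block = stims_per_block, stim_on_s = stim_on_s,
            stim_off_s = stim_off_s, tr_s = tr_s)
  class(p) <- "localizer_params"
  p
}

#' Generate one blocked localizer run
#'
#' Block order is seeded-random under the constraint that every category
#' appears exactly once in each quarter of the run; fixation periods open
#' each quarter and close the run.
#'
#' @param seed integer seed.
#' @param run_id 1-based run index (part of the seed stream).
#' @param params a [localizer_params] list.
#' @return an \code{event_design} with block-level events.
#' @examples
#' d <- generate_localizer_design(seed = 1)
#' design_span(d)  # 336
#' @export
generate_localizer_design <- function(seed, run_id = 1L,
                                      params = localizer_params()) {
  p <- params
  stim_cycle <- p$stim_on_s + p$stim_off_s
  if (abs(p$stims_per_block * stim_cycle - p$block_duration_s) > 1e-9) {
    stop("within-block stimulus timing does not fill the block duration")
  }
  n_cat <- length(p$categories)
  order_mat <- with_seed(child_seed(seed, "localizer", run_id), {
    vapply(seq_len(p$blocks_per_category),
           function(q) sample(p$categories), character(n_cat))
  })
  onset <- 0
  rows <- list()
  for (q in seq_len(p$blocks_per_category)) {
    rows[[length(rows) + 1L]] <- data.frame(
      onset = onset, duration = p$fixation_duration_s,
      condition = "fixation", trial_id = NA_integer_, stringsAsFactors = FALSE)
    onset <- onset + p$fixation_duration_s
    for (categ in order_mat[, q]) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = onset, duration = p$block_duration_s,
        condition = categ, trial_id = NA_integer_, stringsAsFactors = FALSE)
      onset <- onset + p$block_duration_s
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    onset = onset, duration = p$fixation_duration_s,
    condition = "fixation", trial_id = NA_integer_, stringsAsFactors = FALSE)
  onset <- onset + p$fixation_duration_s
  events <- do.call(rbind, rows)
  if (onset %% p$tr_s != 0) {
    stop(sprintf("localizer span %g s is not a multiple of tr_s = %g s",
                 onset, p$tr_s))
  }
  new_event_design(events, run_id, p$tr_s, as.integer(onset / p$tr_s))
}

#' First-order condition-transition counts of a design
#'
#' Diagnostic for the seeded-random counterbalancing: counts how often each
#' condition is immediately followed by each other condition.
#'
#' @param design an \code{event_design}.
#' @return a square integer table (from-condition x to-condition).
#' @export
transition_counts <- function(design) {
  cond <- design$events$condition
  if (length(cond) < 2) {
    lv <- unique(cond)
    return(table(factor(character(), lv), factor(character(), lv)))
  }
  lv <- sort(unique(cond))
  table(from = factor(cond[-length(cond)], lv), to = factor(cond[-1], lv))
}

#' Write / read a design (with optional behavior) as a BIDS-style events table
#'
#' Tab-separated text with columns \code{onset}, \code{duration},
#' \code{trial_type}, \code{trial_id}, \code{response},
#' \code{response_time}; missing values are written as \code{n/a}.
#' Onsets are seconds from run start (0-based time).
#'
#' @param design an \code{event_design}.
#' @param behavior optional behavioral records from [simulate_behavior].
#' @param path file path.
#' @return \code{read_events_tsv} returns a list with the reconstructed
#'   \code{event_design} and, when present, the behavior data frame.
#' @export
write_events_tsv <- function(design, path, behavior = NULL) {
  ev <- design$events
  df <- data.frame(onset = ev$onset, duration = ev$duration,
                   trial_type = ev$condition, trial_id = ev$trial_id,
                   response = NA_character_, response_time = NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(behavior)) {
    i <- match(df$trial_id, behavior$trial_id)
    df$response <- behavior$response[i]
    df$response_time <- behavior$rt_s[i]
  }
  header <- sprintf("# run_id=%s tr_s=%g n_scans=%d", design$run_id,
                    design$tr_s, design$n_scans)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df[] <- lapply(df, function(col) {
    col <- if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    col[is.na(col) | col == "NA"] <- "n/a"
    col
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param path file written by [write_events_tsv].
#' @export
read_events_tsv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- regmatches(header, gregexpr("[a-z_]+=[-0-9.e]+", header))[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.delim(path, skip = 1, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  design <- new_event_design(
    data.frame(onset = df$onset, duration = df$duration,
               condition = df$trial_type, trial_id = df$trial_id,
               stringsAsFactors = FALSE),
    run_id = as.integer(vals[["run_id"]]),
    tr_s = as.numeric(vals[["tr_s"]]),
    n_scans = as.integer(vals[["n_scans"]]))
  behavior <- NULL
  if (any(!is.na(df$response))) {
    keep <- !is.na(df$trial_id)
    behavior <- data.frame(trial_id = df$trial_id[keep],
                           condition = df$trial_type[keep],
                           response = df$response[keep],
                           rt_s = df$response_time[keep],
                           stringsAsFactors = FALSE)
  }
  list(design = design, behavior = behavior)
}
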