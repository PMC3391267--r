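#' Parameters of the simulated whole-part discrimination behavior
#'
#' Per-condition probability of a correct response defaults to the group
#' accuracies the generator is calibrated to emulate (veridical 84.7 %,
#' scrambled 72.7 %), with a no-response rate of 0.1 %.  Response times are
#' drawn from a shifted lognormal; the study reports no RT means, so the RT
#' parameters are free configuration with the veridical mean constrained
#' below the scrambled mean by default.
#'
#' @param p_correct named vector of P(correct) per condition.
#' @param p_no_response probability of a missing response on any trial.
#' @param rt_shift_s non-decision shift of the RT distribution, seconds.
#' @param rt_meanlog named lognormal location per condition (log seconds).
#' @param rt_sdlog lognormal scale.
#' @export
behavior_params <- function(p_correct = c(veridical = 0.847, scrambled = 0.727),
                            p_no_response = 0.001,
                            rt_shift_s = 0.3,
                            rt_meanlog = c(veridical = log(0.55),
                                           scrambled = log(0.75)),
                            rt_sdlog = 0.25) {
  if (any(p_correct < 0 | p_correct > 1)) {
    stop("p_correct must lie in [0, 1]")
  }
  if (p_no_response < 0 || p_no_response > 1) {
    stop("p_no_response must lie in [0, 1]")
  }
  p <- list(p_correct = p_correct, p_no_response = p_no_response,
            rt_shift_s = rt_shift_s, rt_meanlog = rt_meanlog,
            rt_sdlog = rt_sdlog)
  class(p) <- "behavior_params"
  p
}

#' Simulate behavioral responses for an event-related run
#'
#' One record per non-fixation trial.  A trial is first given a response /
#' no-response draw; responded trials are correct with the condition's
#' \code{p_correct} and carry a shifted-lognormal RT.  Unresponded trials
#' have response \code{"none"} and no RT.
#'
#' @param design an \code{event_design} from [generate_experimental_design].
#' @param params a [behavior_params] list.
#' @param seed integer seed; deterministic per (design run, seed).
#' @return data frame: trial_id, condition, response
#'   (\code{correct}/\code{incorrect}/\code{none}), rt_s.
#' @export
simulate_behavior <- function(design, params = behavior_params(), seed = 1L) {
  ev <- design$events
  stim <- ev[!is.na(ev$trial_id), , drop = FALSE]
  n <- nrow(stim)
  pc <- params$p_correct[stim$condition]
  if (anyNA(pc)) stop("p_correct missing for some condition in the design")
  with_seed(child_seed(seed, "behavior", design$run_id), {
    responded <- stats::runif(n) >= params$p_no_response
    correct <- stats::runif(n) < pc
    rt <- params$rt_shift_s +
      stats::rlnorm(n, meanlog = params$rt_meanlog[stim$condition],
                    sdlog = params$rt_sdlog)
    data.frame(
      trial_id = stim$trial_id,
      condition = stim$condition,
      response = ifelse(!responded, "none",
                        ifelse(correct, "correct", "incorrect")),
      rt_s = ifelse(responded, rt, NA_real_),
      stringsAsFactors = FALSE)
  })
}
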