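#' Paired t test with Cohen's d
#'
#' \eqn{t = \bar d / (s_d / \sqrt n)} on the pairwise differences after
#' deletion of pairs with a missing member; two-tailed p on n - 1 degrees
#' of freedom.  The effect size is Cohen's d for paired designs,
#' \eqn{\bar d / s_d}.
#'
#' @param values_a,values_b paired numeric vectors.
#' @return a \code{t_test_result}: t, df, p, d, n, mean_diff.
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  ok <- !is.na(values_a) & !is.na(values_b)
  d <- values_a[ok] - values_b[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(structure(list(t = NA_real_, df = n - 1L, p = NA_real_,
                          d = NA_real_, n = n, mean_diff = mean(d),
                          degenerate = TRUE),
                     class = "t_test_result"))
  }
  tval <- mean(d) / (sdd / sqrt(n))
  structure(list(t = tval, df = n - 1L,
                 p = 2 * stats::pt(-abs(tval), n - 1),
                 d = mean(d) / sdd, n = n, mean_diff = mean(d),
                 degenerate = FALSE),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("paired t: degenerate (zero-variance differences), n = %d\n", x$n))
  } else {
    cat(sprintf("t(%d) = %.3f, p = %.4g, Cohen's d = %.3f\n",
                x$df, x$t, x$p, x$d))
  }
  invisible(x)
}

#' Partial eta squared of a 1-df ANOVA effect
#'
#' \eqn{\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)}.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return value in [0, 1).
#' @examples
#' partial_eta_sq(5.09, 1, 12)  # 0.2978
#' @export
partial_eta_sq <- function(F, df1, df2) {
  stopifnot(F >= 0, df1 >= 1, df2 >= 1)
  F * df1 / (F * df1 + df2)
}

# scale weights so positive part sums to 1 and negative part to -1:
# the contrast score is then a difference of cell means
normalize_contrast <- function(w) {
  pos <- sum(w[w > 0]); neg <- -sum(w[w < 0])
  if (pos == 0 || neg == 0) stop("contrast must have positive and negative weights")
  out <- w
  out[w > 0] <- w[w > 0] / pos
  out[w < 0] <- w[w < 0] / neg
  out
}

#' One-degree-of-freedom within-subject ANOVA effect
#'
#' For a fully within-subject factorial design every main effect and
#' interaction with 1 numerator df is equivalent to a paired t test on
#' per-subject contrast scores: with weights normalized so the score is a
#' difference of cell means, \eqn{F = t^2} on (1, n-1) df, and partial
#' eta squared follows from the F.  Subjects with any missing cell are
#' dropped listwise, and the reported df reflect the subjects actually
#' analyzed.
#'
#' @param cell_table numeric matrix, subjects x cells (4 cells for a 2x2,
#'   8 for a 2x2x2), with cell names as columns.
#' @param contrast_weights one weight per cell (named or in column order)
#'   with both signs present.
#' @param name label for the effect.
#' @return an \code{anova_effect}: name, F, df1 = 1, df2, p,
#'   partial_eta_sq, n, mean_score.
#' @export
rm_anova_1df <- function(cell_table, contrast_weights, name = "effect") {
  y <- as.matrix(cell_table)
  w <- contrast_weights
  if (!is.null(names(w))) {
    if (!all(names(w) %in% colnames(y))) stop("contrast names not in cell table")
    w <- w[colnames(y)]
    w[is.na(w)] <- 0
  }
  if (length(w) != ncol(y)) stop("one contrast weight per cell required")
  w <- normalize_contrast(w)
  complete <- rowSums(is.na(y)) == 0
  y <- y[complete, , drop = FALSE]
  n <- nrow(y)
  if (n < 2) stop("fewer than 2 subjects with complete cells")
  score <- drop(y %*% w)
  tt <- paired_t(score, rep(0, n))
  Fv <- if (isTRUE(tt$degenerate)) 0 else tt$t^2
  structure(list(name = name, F = Fv, df1 = 1L, df2 = n - 1L,
                 p = if (isTRUE(tt$degenerate)) NA_real_ else
                   stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
                 partial_eta_sq = partial_eta_sq(Fv, 1, n - 1),
                 n = n, mean_score = mean(score)),
            class = "anova_effect")
}

#' @export
print.anova_effect <- function(x, ...) {
  cat(sprintf("%s: F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$name, x$df1, x$df2, x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' Standard 1-df contrasts for the 2x2 (condition x response) design
#'
#' Cells are veridical/scrambled x correct/incorrect.  Returns weights for
#' the condition main effect, response main effect and their interaction.
#' @export
contrasts_2x2 <- function() {
  cn <- cell_names
  list(
    condition = stats::setNames(c(1, 1, -1, -1), cn),
    response = stats::setNames(c(1, -1, 1, -1), cn),
    interaction = stats::setNames(c(1, -1, -1, 1), cn))
}

#' Group behavioral summary with paired tests
#'
#' Per subject and condition: response accuracy (correct among responded
#' trials) and, by default, mean RT over correct trials only.  Group-level
#' paired t tests compare conditions on both measures.
#'
#' @param behavior_by_subject named list; each element one subject's
#'   behavioral records (rbind of [simulate_behavior] outputs, or the
#'   equivalent for real data).
#' @param rt_correct_only restrict RT means to correct trials (default TRUE).
#' @return a \code{behavioral_summary}: per-subject table, group means,
#'   accuracy and RT paired t results.
#' @export
behavioral_summary <- function(behavior_by_subject, rt_correct_only = TRUE) {
  if (length(behavior_by_subject) < 2) stop("need at least 2 subjects")
  per <- do.call(rbind, lapply(names(behavior_by_subject), function(subj) {
    b <- behavior_by_subject[[subj]]
    b <- b[b$response != "none", , drop = FALSE]
    do.call(rbind, lapply(unique(b$condition), function(cond) {
      bc <- b[b$condition == cond, , drop = FALSE]
      if (nrow(bc) == 0) {
        warning(sprintf("subject %s has no valid trials in condition %s; dropped",
                        subj, cond))
        return(NULL)
      }
      rt_rows <- if (rt_correct_only) bc$response == "correct" else TRUE
      data.frame(subject = subj, condition = cond,
                 accuracy = mean(bc$response == "correct"),
                 mean_rt_s = mean(bc$rt_s[rt_rows], na.rm = TRUE),
                 n_trials = nrow(bc), stringsAsFactors = FALSE)
    }))
  }))
  wide <- function(measure) {
    v <- stats::reshape(per[, c("subject", "condition", measure)],
                        direction = "wide", idvar = "subject",
                        timevar = "condition")
    v
  }
  acc <- wide("accuracy")
  rt <- wide("mean_rt_s")
  acc_t <- tryCatch(paired_t(acc$accuracy.veridical, acc$accuracy.scrambled),
                    error = function(e) NULL)
  rt_t <- tryCatch(paired_t(rt$mean_rt_s.veridical, rt$mean_rt_s.scrambled),
                   error = function(e) NULL)
  group <- stats::aggregate(cbind(accuracy, mean_rt_s) ~ condition, per, mean)
  structure(list(per_subject = per, group_means = group,
                 accuracy_test = acc_t, rt_test = rt_t),
            class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat("Group behavior:\n")
  print(x$group_means)
  if (!is.null(x$accuracy_test)) {
    cat("accuracy veridical vs scrambled: "); print(x$accuracy_test)
  }
  if (!is.null(x$rt_test)) {
    cat("RT veridical vs scrambled: "); print(x$rt_test)
  }
  invisible(x)
}
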