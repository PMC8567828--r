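#' Type-2 ROC AUC (metamemory sensitivity)
#'
#' Nonparametric sensitivity of confidence to one's own accuracy. Sweeping
#' confidence criteria c = 10..1, the type-2 hit rate is
#' `P(conf >= c | correct)` and the type-2 false-alarm rate is
#' `P(conf >= c | incorrect)`; the AUC is the trapezoidal area under the
#' resulting ROC anchored at (0,0) and (1,1). With ties credited half, this
#' equals the rank statistic `U / (n1 * n0)`. Invariant to any strictly
#' monotone transformation of confidence. 0.5 is chance, 1 perfect
#' metacognition.
#'
#' @param correct logical/0-1 vector of trial correctness.
#' @param confidence numeric confidence ratings (any ordinal scale).
#' @return object of class `sensitivity_score`: `auc` (`NA` when only one
#'   outcome class is present), `n_correct`, `n_incorrect`, `roc_points`
#'   (data.frame `far`, `hr` from (0,0) to (1,1)).
#' @export
type2_auc <- function(correct, confidence) {
  stopifnot(length(correct) == length(confidence))
  correct <- as.logical(correct)
  ok <- !is.na(correct) & !is.na(confidence)
  correct <- correct[ok]; confidence <- confidence[ok]
  n1 <- sum(correct); n0 <- sum(!correct)
  if (n1 == 0L || n0 == 0L) {
    return(structure(list(auc = NA_real_, n_correct = n1, n_incorrect = n0,
                          roc_points = NULL),
                     class = "sensitivity_score"))
  }
  crits <- sort(unique(confidence), decreasing = TRUE)
  hr <- vapply(crits, function(c0) mean(confidence[correct] >= c0), 0)
  far <- vapply(crits, function(c0) mean(confidence[!correct] >= c0), 0)
  far <- c(0, far, 1); hr <- c(0, hr, 1)
  auc <- sum(diff(far) * (utils::head(hr, -1) + utils::tail(hr, -1)) / 2)
  structure(list(auc = auc, n_correct = n1, n_incorrect = n0,
                 roc_points = data.frame(far = far, hr = hr)),
            class = "sensitivity_score")
}

#' @export
print.sensitivity_score <- function(x, ...) {
  cat(sprintf("<sensitivity_score> AUC = %s (%d correct, %d incorrect)\n",
              format(x$auc, digits = 4), x$n_correct, x$n_incorrect))
  invisible(x)
}

#' Overnight change in metamemory sensitivity
#'
#' @param pre,post `sensitivity_score` objects (or numeric AUCs) for the
#'   pre- and post-sleep sessions of the same participant/condition.
#' @return `post - pre` AUC; `NA` propagates.
#' @export
overnight_change <- function(pre, post) {
  a_pre <- if (inherits(pre, "sensitivity_score")) pre$auc else pre
  a_post <- if (inherits(post, "sensitivity_score")) post$auc else post
  a_post - a_pre
}

#' Per-participant sensitivity table from trial records
#'
#' Pools all trials within each participant x session (x condition when
#' present) cell and computes the type-2 AUC.
#'
#' @param trials data.frame with columns `participant`, `session`,
#'   `correct`, `confidence`, and optionally `condition`.
#' @return data.frame `(participant[, condition], session, auc, n_correct,
#'   n_incorrect)`.
#' @export
sensitivity_table <- function(trials) {
  keys <- intersect(c("participant", "condition", "session"), names(trials))
  split_f <- interaction(trials[keys], drop = TRUE)
  rows <- lapply(split(trials, split_f), function(d) {
    s <- type2_auc(d$correct, d$confidence)
    cbind(d[1, keys, drop = FALSE],
          data.frame(auc = s$auc, n_correct = s$n_correct,
                     n_incorrect = s$n_incorrect))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant), , drop = FALSE]
}

#' Paired behavioral comparison with family-wise correction
#'
#' Dependent t test on paired scores, paired Cohen's d
#' (`mean(diff) / sd(diff)`), and Holm step-down adjustment of the
#' p value over a declared family of comparisons.
#'
#' @param scores_a,scores_b paired numeric vectors (n >= 3).
#' @param family_p raw p values of the other comparisons in the family
#'   (this test's raw p is appended before Holm adjustment).
#' @param alternative passed to [stats::t.test()].
#' @return list: `t`, `df`, `p_raw`, `p_adjusted` (Holm, for this
#'   comparison), `cohens_d`, `mean_diff`, `degenerate` (TRUE when the
#'   differences have zero variance; statistics are then `NA`).
#' @export
paired_comparison <- function(scores_a, scores_b, family_p = numeric(0),
                              alternative = "two.sided") {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 3L)
  d <- scores_a - scores_b
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + stats::sd(scores_a) + 1)) {
    return(list(t = NA_real_, df = length(d) - 1L, p_raw = NA_real_,
                p_adjusted = NA_real_, cohens_d = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE,
                      alternative = alternative)
  p_all <- stats::p.adjust(c(tt$p.value, family_p), method = "holm")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value, p_adjusted = p_all[1],
       cohens_d = mean(d) / stats::sd(d), mean_diff = mean(d),
       degenerate = FALSE)
}
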