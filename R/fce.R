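# Condition summaries, flanker congruency effects, within-subject error bars,
# and the composite speed-accuracy feedback score.

#' Per-subject condition summaries: mean error rate and median correct RT
#'
#' Aggregates a classified trial table into one row per subject x condition x
#' congruency, where the condition is the experiment's analysis factor (SOA;
#' contrast-change time with "none" for the constant control; or location
#' certainty Fixed / VariableSame / VariableDiff). Practice trials and, for
#' the location experiment, excluded first-of-block trials are dropped. The
#' error rate is `1 - n_correct / n_trials`; the median RT is computed over
#' usable (correct, >= cutoff) trials only. Cells with no usable RT are
#' flagged and carry `NA` medians.
#'
#' @param table trial table processed by [classify_trials()] (and
#'   [label_carryover()] for the location experiment).
#' @return data frame with columns `subject_id`, `condition`, `congruency`,
#'   `n_trials`, `n_correct`, `er`, `median_rt_ms`, `empty_cell`.
#' @export
summarize_conditions <- function(table) {
  if (is.null(table$correct)) stopf("run classify_trials() first")
  keep <- !table$is_practice
  cond <- condition_of(table)
  keep <- keep & !is.na(cond)
  tb <- table[keep, , drop = FALSE]
  cond <- cond[keep]
  key <- interaction(tb$subject_id, cond, tb$congruency, drop = TRUE,
                     sep = "\r")
  split_idx <- split(seq_len(nrow(tb)), key)
  rows <- lapply(split_idx, function(ii) {
    x <- tb[ii, , drop = FALSE]
    usable <- x$rt_ms[x$usable_for_rt]
    data.frame(subject_id = x$subject_id[1L],
               condition = cond[ii[1L]],
               congruency = x$congruency[1L],
               n_trials = nrow(x),
               n_correct = sum(x$correct),
               er = 1 - sum(x$correct) / nrow(x),
               median_rt_ms = if (length(usable)) stats::median(usable)
                              else NA_real_,
               empty_cell = length(usable) == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  lev <- condition_levels(tb$experiment[1L])
  out <- out[order(out$subject_id, match(out$condition, lev),
                   out$congruency), ]
  rownames(out) <- NULL
  if (any(out$empty_cell)) {
    warning(sprintf("%d summary cell(s) have no usable RTs and are flagged",
                    sum(out$empty_cell)), call. = FALSE)
  }
  out
}

#' Flanker congruency effects per subject and condition
#'
#' The congruency effect is incongruent minus congruent, for both the error
#' rate and the median correct RT, so positive values index interference.
#'
#' @param summaries output of [summarize_conditions()]; both congruency levels
#'   must be present in every subject x condition cell.
#' @return data frame with `subject_id`, `condition`, `fce_er`, `fce_rt_ms`.
#' @export
compute_fce <- function(summaries) {
  key <- interaction(summaries$subject_id, summaries$condition, drop = TRUE,
                     sep = "\r")
  rows <- lapply(split(seq_len(nrow(summaries)), key), function(ii) {
    x <- summaries[ii, , drop = FALSE]
    ic <- match("INCONGRUENT", x$congruency)
    co <- match("CONGRUENT", x$congruency)
    if (is.na(ic) || is.na(co)) {
      stopf("subject %s, condition %s: missing a congruency level",
            x$subject_id[1L], x$condition[1L])
    }
    data.frame(subject_id = x$subject_id[1L],
               condition = x$condition[1L],
               fce_er = x$er[ic] - x$er[co],
               fce_rt_ms = x$median_rt_ms[ic] - x$median_rt_ms[co],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Within-subject standard errors (Cousineau-Morey)
#'
#' Removes between-subject offsets by centering each subject at the grand mean
#' (subtract the subject mean, add back the grand mean), applies Morey's bias
#' correction `sqrt(k / (k - 1))` for `k` conditions, and returns the standard
#' error of the corrected values per condition. This is the error bar used for
#' within-subject designs.
#'
#' @param x numeric matrix, one row per subject, one column per condition;
#'   complete cells required.
#' @return named vector of per-condition standard errors.
#' @export
within_subject_se <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) stopf("need >= 2 subjects and >= 2 conditions")
  if (anyNA(x)) stopf("complete cells required")
  centered <- x - rowMeans(x) + mean(x)
  apply(centered, 2L, stats::sd) * sqrt(k / (k - 1)) / sqrt(n)
}

#' Composite speed-accuracy block score
#'
#' The end-of-block feedback score. Speed credits each responded trial by
#' `(ln 3000 - ln(rt + 1000)) / (ln 3000 - ln 1300)`, averaged over all
#' `n_total` trials of the block (missing responses contribute 0 to the sum
#' but still count in the denominator); a 300-ms response earns exactly 1 and
#' a 2000-ms response 0. Accuracy is the proportion correct. The unweighted
#' score is `(accuracy - 0.5) / 0.5 * speed * 100`; chance-level accuracy
#' zeroes it. With `weights = c(accuracy, speed)` summing to 1, the score is
#' the convex combination `100 * (w_acc * (accuracy - 0.5)/0.5 + w_spd *
#' speed)` instead (the dynamic-contrast experiments weight accuracy at 80%,
#' the location experiment at 75%). Either form is clipped to `[0, 100]`.
#'
#' @param rt_ms response times (ms, relative to target onset) of the block's
#'   responded trials; every value must exceed -1000.
#' @param n_total total number of trials in the block (>= 1).
#' @param n_correct number of correct trials.
#' @param weights optional `c(w_accuracy, w_speed)` summing to 1; `NULL` gives
#'   the unweighted (multiplicative) score.
#' @return list with `speed`, `accuracy`, `score`.
#' @export
composite_score <- function(rt_ms, n_total, n_correct, weights = NULL) {
  if (n_total < 1L) stopf("n_total must be >= 1")
  if (n_correct > n_total) stopf("n_correct exceeds n_total")
  if (any(rt_ms <= -1000)) stopf("response times must exceed -1000 ms")
  speed <- sum((log(3000) - log(rt_ms + 1000)) /
                 (log(3000) - log(1300))) / n_total
  accuracy <- n_correct / n_total
  raw <- if (is.null(weights)) {
    (accuracy - 0.5) / 0.5 * speed * 100
  } else {
    if (length(weights) != 2L || abs(sum(weights) - 1) > 1e-8) {
      stopf("weights must be two values summing to 1")
    }
    100 * (weights[1L] * (accuracy - 0.5) / 0.5 + weights[2L] * speed)
  }
  list(speed = speed, accuracy = accuracy,
       score = min(max(raw, 0), 100))
}

#' Composite scores per subject and block
#'
#' @param table classified trial table.
#' @param weights optional accuracy/speed weights, as in [composite_score()].
#' @return data frame with one score row per subject x block (practice
#'   included, flagged).
#' @export
block_scores <- function(table, weights = NULL) {
  if (is.null(table$correct)) stopf("run classify_trials() first")
  key <- interaction(table$subject_id, table$is_practice, table$block_index,
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(table)), key), function(ii) {
    x <- table[ii, , drop = FALSE]
    responded <- x$response != "NONE"
    sc <- composite_score(x$rt_ms[responded], nrow(x), sum(x$correct),
                          weights)
    data.frame(subject_id = x$subject_id[1L],
               block_index = x$block_index[1L],
               is_practice = x$is_practice[1L],
               speed = sc$speed, accuracy = sc$accuracy, score = sc$score)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, !out$is_practice, out$block_index), ]
  rownames(out) <- NULL
  out
}
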