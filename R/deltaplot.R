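# Delta-plot time-course analysis (De Jong-style).
#
# Per subject and condition, correct RTs from the two congruency levels are
# reduced to nine decile estimates (10..90%). Each percentile bin contributes
# an x-value (the mean of the congruent and incongruent percentile RTs) and a
# y-value (their difference, the congruency effect at that bin). A per-subject
# OLS line through the nine points summarizes how interference changes across
# the RT distribution; group inference tests the mean slope against zero per
# condition with Benjamini-Hochberg correction across the experiment's
# conditions.

DELTA_LEVELS <- seq(10, 90, by = 10)

#' Nine percentile interval values of a correct-RT distribution
#'
#' Percentiles 10, 20, ..., 90 estimated by linear interpolation between order
#' statistics (R's default type-7 estimator; the choice is fixed and
#' documented because published procedures rarely name one).
#'
#' @param rts numeric vector of correct RTs (ms).
#' @param levels percentile levels (percent).
#' @param min_trials minimum number of RTs required (default 10); fewer gives
#'   an error — higher-level drivers catch it, flag the cell, and exclude the
#'   subject x condition with a warning.
#' @return nondecreasing numeric vector, one value per level.
#' @export
rt_percentiles <- function(rts, levels = DELTA_LEVELS, min_trials = 10L) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < min_trials) {
    stopf("need at least %d correct RTs, got %d", min_trials, length(rts))
  }
  unname(stats::quantile(rts, probs = levels / 100, type = 7))
}

#' Per-subject delta plot from the two congruency RT distributions
#'
#' @param congruent_rts,incongruent_rts correct RTs of the two congruency
#'   levels (ms).
#' @param min_trials per-cell minimum passed to [rt_percentiles()].
#' @return list of class `delta_plot` with `percentiles`, `bin_rt_ms` (mean of
#'   the two percentile values per bin), `fce_rt_ms` (incongruent minus
#'   congruent per bin), and `slope`/`intercept_ms` (NA until [fit_slope()]).
#' @export
subject_delta <- function(congruent_rts, incongruent_rts, min_trials = 10L) {
  qc <- rt_percentiles(congruent_rts, min_trials = min_trials)
  qi <- rt_percentiles(incongruent_rts, min_trials = min_trials)
  structure(list(percentiles = DELTA_LEVELS,
                 bin_rt_ms = (qc + qi) / 2,
                 fce_rt_ms = qi - qc,
                 slope = NA_real_,
                 intercept_ms = NA_real_),
            class = "delta_plot")
}

#' Fit the delta-plot slope by ordinary least squares
#'
#' Regresses the per-bin congruency effect on the per-bin RT. The slope is
#' dimensionless (ms of effect per ms of RT).
#'
#' @param dp a `delta_plot` from [subject_delta()].
#' @return the `delta_plot` with `slope` and `intercept_ms` filled in; a
#'   degenerate x (all bins at the same RT) leaves the slope `NA` with a
#'   `degenerate` flag.
#' @export
fit_slope <- function(dp) {
  x <- dp$bin_rt_ms
  y <- dp$fce_rt_ms
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    dp$slope <- NA_real_
    dp$intercept_ms <- mean(y)
    dp$degenerate <- TRUE
    return(dp)
  }
  dp$slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  dp$intercept_ms <- mean(y) - dp$slope * mean(x)
  dp$degenerate <- FALSE
  dp
}

#' Delta plots for every subject x condition of a trial table
#'
#' Builds [subject_delta()] + [fit_slope()] for each subject x condition cell,
#' using usable (correct) RTs. Cells with fewer than `min_trials` usable RTs
#' in either congruency level are excluded with one collective warning.
#'
#' @param table classified (and, for the location experiment, carry-over
#'   labeled) trial table.
#' @param min_trials per-cell minimum number of correct RTs.
#' @return list with `bins` (tidy data frame: subject, condition, percentile,
#'   bin_rt_ms, fce_rt_ms) and `slopes` (subject, condition, slope,
#'   intercept_ms).
#' @export
delta_plots <- function(table, min_trials = 10L) {
  if (is.null(table$usable_for_rt)) stopf("run classify_trials() first")
  cond <- condition_of(table)
  keep <- !table$is_practice & !is.na(cond) & table$usable_for_rt
  tb <- table[keep, , drop = FALSE]
  cond <- cond[keep]
  bins <- list()
  slopes <- list()
  skipped <- character()
  present <- intersect(condition_levels(tb$experiment[1L]), unique(cond))
  for (s in sort(unique(tb$subject_id))) {
    for (cc in present) {
      ii <- tb$subject_id == s & cond == cc
      crt <- tb$rt_ms[ii & tb$congruency == "CONGRUENT"]
      irt <- tb$rt_ms[ii & tb$congruency == "INCONGRUENT"]
      if (length(crt) < min_trials || length(irt) < min_trials) {
        skipped <- c(skipped, sprintf("subject %s / %s", s, cc))
        next
      }
      dp <- fit_slope(subject_delta(crt, irt, min_trials = min_trials))
      bins[[length(bins) + 1L]] <- data.frame(
        subject_id = s, condition = cc, percentile = dp$percentiles,
        bin_rt_ms = dp$bin_rt_ms, fce_rt_ms = dp$fce_rt_ms,
        stringsAsFactors = FALSE)
      slopes[[length(slopes) + 1L]] <- data.frame(
        subject_id = s, condition = cc, slope = dp$slope,
        intercept_ms = dp$intercept_ms, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning(sprintf("excluded %d cell(s) below min_trials: %s",
                    length(skipped),
                    paste(utils::head(skipped, 5L), collapse = "; ")),
            call. = FALSE)
  }
  list(bins = do.call(rbind, bins), slopes = do.call(rbind, slopes))
}

#' Group test of mean delta-plot slopes against zero
#'
#' One-sample two-sided t test of the subject slopes per condition, with
#' Benjamini-Hochberg step-up adjustment across the experiment's conditions
#' (nine SOAs, five contrast-change conditions, or three location conditions).
#' Cohen's d is mean/SD. Zero slope variance with a nonzero mean is reported
#' as an infinite t with a flag.
#'
#' @param slopes data frame with `subject_id`, `condition`, `slope` (the
#'   `slopes` element of [delta_plots()]).
#' @return data frame per condition: n, mean slope, t, df, p, BH-adjusted p,
#'   Cohen's d, and a `degenerate` flag.
#' @export
group_slope_test <- function(slopes) {
  conds <- unique(slopes$condition)
  rows <- lapply(conds, function(cc) {
    x <- slopes$slope[slopes$condition == cc]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) stopf("condition %s: need >= 2 subjects", cc)
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) {
      t <- if (m == 0) 0 else sign(m) * Inf
      p <- if (m == 0) 1 else 0
      degen <- m != 0
      d <- if (m == 0) 0 else sign(m) * Inf
    } else {
      t <- m / (s / sqrt(n))
      p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
      d <- m / s
      degen <- FALSE
    }
    data.frame(condition = cc, n = n, mean_slope = m, t = t, df = n - 1,
               p = p, cohens_d = d, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out[, c("condition", "n", "mean_slope", "t", "df", "p", "p_bh",
          "cohens_d", "degenerate")]
}

#' Group-level delta-plot curves
#'
#' Means over subjects of the per-bin RT (x) and congruency effect (y), per
#' condition, for plotting.
#'
#' @param bins the `bins` element of [delta_plots()].
#' @return data frame: condition, percentile, mean bin RT, mean effect, n.
#' @export
group_delta_plot <- function(bins) {
  key <- interaction(bins$condition, bins$percentile, drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(bins)), key), function(ii) {
    x <- bins[ii, , drop = FALSE]
    data.frame(condition = x$condition[1L], percentile = x$percentile[1L],
               bin_rt_ms = mean(x$bin_rt_ms), fce_rt_ms = mean(x$fce_rt_ms),
               n = nrow(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$percentile), ]
  rownames(out) <- NULL
  out
}

#' Linear and quadratic trend tests over delta-plot bins
#'
#' Orthogonal polynomial contrasts of degree 1 and 2 over the bin index
#' (1..9), computed per subject and tested against zero across subjects, per
#' condition. Contrasts are over the bin index, not the bin RT, because the RT
#' spacing of bins differs across subjects, whereas index contrasts stay
#' orthogonal by construction.
#'
#' @param bins the `bins` element of [delta_plots()]; complete nine-bin data
#'   per subject x condition required.
#' @return data frame: condition, trend ("linear"/"quadratic"), mean contrast
#'   estimate, t, df, p.
#' @export
polynomial_contrasts <- function(bins) {
  cp <- stats::contr.poly(length(DELTA_LEVELS))
  rows <- list()
  for (cc in unique(bins$condition)) {
    sub <- bins[bins$condition == cc, , drop = FALSE]
    est <- vapply(split(sub, sub$subject_id), function(x) {
      if (nrow(x) != length(DELTA_LEVELS)) {
        stopf("condition %s: incomplete bins for subject %s", cc,
              x$subject_id[1L])
      }
      y <- x$fce_rt_ms[order(x$percentile)]
      c(sum(cp[, 1L] * y), sum(cp[, 2L] * y))
    }, numeric(2))
    for (j in 1:2) {
      e <- est[j, ]
      n <- length(e)
      se <- stats::sd(e) / sqrt(n)
      t <- if (se == 0) 0 else mean(e) / se
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cc, trend = c("linear", "quadratic")[j],
        estimate = mean(e), t = t, df = n - 1,
        p = 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
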