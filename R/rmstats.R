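# Repeated-measures inference: two-way within-subject ANOVA with
# Greenhouse-Geisser sphericity adjustment, simple effects, the carry-over
# contrast of the location-uncertainty experiment, and a priori power.
#
# The ANOVA uses the classical univariate decomposition: each within-subject
# effect is tested against its own effect x subject interaction, which matches
# the degrees-of-freedom patterns standard in this literature (e.g. F(1, n-1)
# for a two-level congruency factor).

orthonormal_contrasts <- function(k) stats::contr.poly(k) # columns orthonormal

#' Greenhouse-Geisser (Box) epsilon
#'
#' Sphericity-departure index computed from the double-centered covariance
#' matrix of the k within-condition scores:
#' `eps = tr(A)^2 / ((k - 1) * sum(A^2))` with `A = C S C`, `C = I - J/k`.
#' Bounded in `[1/(k - 1), 1]`; equals 1 under compound symmetry (and always
#' for k = 2). Adjusted degrees of freedom are `eps` times the raw ones.
#'
#' @param S symmetric positive semidefinite k x k covariance matrix of the
#'   subject scores across the k levels.
#' @return epsilon in `[1/(k - 1), 1]`.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 2L || ncol(S) != k) stopf("S must be a square matrix with k >= 2")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stopf("S must be symmetric")
  }
  C <- diag(k) - 1 / k
  A <- C %*% S %*% C
  denom <- (k - 1) * sum(A * A)
  if (denom <= 0) return(1)
  eps <- sum(diag(A))^2 / denom
  min(max(eps, 1 / (k - 1)), 1)
}

# Box epsilon for an effect defined by an orthonormal contrast matrix M over
# the cell scores (rows = subjects): eigen-form on M' S M.
epsilon_for_contrast <- function(scores, M) {
  d <- ncol(M)
  if (d == 1L) return(1)
  S <- stats::cov(scores)
  A <- t(M) %*% S %*% M
  eps <- sum(diag(A))^2 / (d * sum(A * A))
  min(max(eps, 1 / d), 1)
}

#' Two-way within-subject ANOVA with Greenhouse-Geisser adjustment
#'
#' Takes subject-level cell scores for a fully crossed a x b within design
#' (one value per subject x level combination; replicate rows are averaged
#' into cell means first). Each effect's error term is its interaction with
#' subjects. Effects with more than one numerator degree of freedom get a
#' Greenhouse-Geisser epsilon (from the covariance of the effect's orthonormal
#' contrast scores), epsilon-scaled degrees of freedom, and a sphericity-
#' adjusted p value; single-df effects have epsilon 1.
#'
#' @param data data frame with one score per row.
#' @param dv,subject,factor_a,factor_b column names.
#' @return data frame, one row per effect (A, B, A:B): sums of squares for
#'   effect and error, raw and adjusted df, epsilon, F, p (adjusted), partial
#'   eta squared.
#' @export
rm_anova_2way <- function(data, dv, subject, factor_a, factor_b) {
  y <- data[[dv]]
  s <- factor(data[[subject]])
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (anyNA(y)) stopf("missing scores")
  n <- nlevels(s)
  a <- nlevels(A)
  b <- nlevels(B)
  if (n < 2L) stopf("need >= 2 subjects")
  # cell means per subject x A x B; every cell must be filled
  cell <- tapply(y, list(s, A, B), mean)
  if (anyNA(cell)) stopf("missing cells: the design must be complete")

  gm <- mean(cell)
  mS <- apply(cell, 1L, mean)
  mA <- apply(cell, 2L, mean)
  mB <- apply(cell, 3L, mean)
  mSA <- apply(cell, c(1L, 2L), mean)
  mSB <- apply(cell, c(1L, 3L), mean)
  mAB <- apply(cell, c(2L, 3L), mean)

  ss_a <- n * b * sum((mA - gm)^2)
  ss_b <- n * a * sum((mB - gm)^2)
  ss_ab <- n * sum((mAB - outer(mA, rep(1, b)) -
                      outer(rep(1, a), mB) + gm)^2)
  ss_as <- b * sum((mSA - outer(mS, rep(1, a)) -
                      outer(rep(1, n), mA) + gm)^2)
  ss_bs <- a * sum((mSB - outer(mS, rep(1, b)) -
                      outer(rep(1, n), mB) + gm)^2)
  ss_s <- a * b * sum((mS - gm)^2)
  ss_tot <- sum((cell - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_as - ss_bs - ss_s

  # epsilon per effect from orthonormal contrast scores of the cell matrix
  flat <- matrix(cell, nrow = n) # subjects x (a*b), A varying fastest
  Ca <- orthonormal_contrasts(a)
  Cb <- orthonormal_contrasts(b)
  one_a <- matrix(1 / sqrt(a), a, 1)
  one_b <- matrix(1 / sqrt(b), b, 1)
  M_a <- kronecker(one_b, Ca) # columns index (b-mean, A contrasts)
  M_b <- kronecker(Cb, one_a)
  M_ab <- kronecker(Cb, Ca)
  eps <- c(A = epsilon_for_contrast(flat, M_a),
           B = epsilon_for_contrast(flat, M_b),
           `A:B` = epsilon_for_contrast(flat, M_ab))

  eff <- data.frame(
    effect = c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":")),
    ss_effect = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_as, ss_bs, ss_abs),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1),
            (a - 1) * (b - 1) * (n - 1)),
    epsilon = as.numeric(eps),
    stringsAsFactors = FALSE)
  eff$ms_effect <- eff$ss_effect / eff$df1
  eff$ms_error <- eff$ss_error / eff$df2
  eff$F <- ifelse(eff$ms_error > 0, eff$ms_effect / eff$ms_error,
                  ifelse(eff$ms_effect == 0, 0, Inf))
  eff$df1_adj <- eff$epsilon * eff$df1
  eff$df2_adj <- eff$epsilon * eff$df2
  eff$p <- stats::pf(eff$F, eff$df1_adj, eff$df2_adj, lower.tail = FALSE)
  eff$partial_eta_sq <- ifelse(eff$ss_effect + eff$ss_error > 0,
                               eff$ss_effect / (eff$ss_effect + eff$ss_error),
                               0)
  attr(eff, "ss_subject") <- ss_s
  attr(eff, "ss_total") <- ss_tot
  eff
}

paired_t_row <- function(diffs, alternative = "two.sided", conf = 0.95) {
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2L) stopf("need >= 2 paired differences")
  m <- mean(diffs)
  se <- stats::sd(diffs) / sqrt(n)
  t <- if (se == 0) (if (m == 0) 0 else sign(m) * Inf) else m / se
  p <- switch(alternative,
    two.sided = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
    greater = stats::pt(t, n - 1, lower.tail = FALSE),
    less = stats::pt(t, n - 1))
  tc <- stats::qt(1 - (1 - conf) / 2, n - 1)
  list(estimate = m, t = t, df = n - 1, p = p,
       ci_lower = m - tc * se, ci_upper = m + tc * se, n = n)
}

#' Simple effects of congruency and pairwise effect-difference contrasts
#'
#' Per condition level, a paired test of incongruent vs. congruent (a
#' one-sample t on the per-subject congruency effect); plus paired contrasts
#' of the effect between every pair of condition levels. No multiplicity
#' correction is applied by default; `adjust = "holm"` is available for
#' exploratory use.
#'
#' @param fce output of [compute_fce()].
#' @param measure `"fce_rt_ms"` or `"fce_er"`.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`;
#'   one-sided modes serve directional hypotheses.
#' @param adjust `"none"` (default) or `"holm"`, applied within each of the
#'   two output tables.
#' @return list with `congruency` (per condition) and `pairwise` (per pair of
#'   conditions) data frames.
#' @export
simple_effects <- function(fce, measure = c("fce_rt_ms", "fce_er"),
                           alternative = c("two.sided", "greater", "less"),
                           adjust = c("none", "holm")) {
  measure <- match.arg(measure)
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  conds <- unique(fce$condition)
  wide <- sapply(conds, function(cc) {
    x <- fce[fce$condition == cc, ]
    x[[measure]][order(x$subject_id)]
  })
  cong <- do.call(rbind, lapply(seq_along(conds), function(j) {
    r <- paired_t_row(wide[, j], alternative)
    data.frame(condition = conds[j], estimate = r$estimate, t = r$t,
               df = r$df, p = r$p, stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(seq_along(conds), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    r <- paired_t_row(wide[, j] - wide[, i], alternative)
    data.frame(condition_1 = conds[i], condition_2 = conds[j],
               estimate = r$estimate, t = r$t, df = r$df, p = r$p,
               stringsAsFactors = FALSE)
  }))
  if (adjust == "holm") {
    cong$p_adj <- stats::p.adjust(cong$p, "holm")
    pw$p_adj <- stats::p.adjust(pw$p, "holm")
  }
  list(congruency = cong, pairwise = pw)
}

#' Congruency-specific location carry-over contrast
#'
#' For the location-uncertainty experiment: per subject and congruency level,
#' the carry-over effect is the median-RT difference between Variable-Diff and
#' Variable-Same trials. The contrast tests whether the carry-over effect is
#' larger on incongruent than congruent trials (paired t, 95% CI on the
#' difference of differences). Subjects missing a Variable-Same cell in either
#' congruency level are excluded with a warning.
#'
#' @param summaries [summarize_conditions()] output for EXP3 (conditions
#'   `VariableSame` / `VariableDiff` present).
#' @param conf confidence level for the interval.
#' @return list with per-congruency mean carry-over effects and the
#'   difference-of-differences estimate, t, df, p, and CI.
#' @export
carryover_contrast <- function(summaries, conf = 0.95) {
  get_cell <- function(s, cond, cg) {
    x <- summaries[summaries$subject_id == s & summaries$condition == cond &
                     summaries$congruency == cg, ]
    if (nrow(x) != 1L || is.na(x$median_rt_ms)) NA_real_ else x$median_rt_ms
  }
  subj <- sort(unique(summaries$subject_id))
  co <- vapply(subj, function(s) {
    get_cell(s, "VariableDiff", "CONGRUENT") -
      get_cell(s, "VariableSame", "CONGRUENT")
  }, numeric(1))
  ic <- vapply(subj, function(s) {
    get_cell(s, "VariableDiff", "INCONGRUENT") -
      get_cell(s, "VariableSame", "INCONGRUENT")
  }, numeric(1))
  ok <- !is.na(co) & !is.na(ic)
  if (any(!ok)) {
    warning(sprintf("excluded %d subject(s) lacking carry-over cells",
                    sum(!ok)), call. = FALSE)
  }
  r <- paired_t_row(ic[ok] - co[ok], "two.sided", conf)
  list(carryover_congruent_ms = mean(co[ok]),
       carryover_incongruent_ms = mean(ic[ok]),
       difference_ms = r$estimate, t = r$t, df = r$df, p = r$p,
       ci_lower = r$ci_lower, ci_upper = r$ci_upper, n = r$n)
}

#' A priori power for within-subject congruency effects
#'
#' Two designs: a paired t test with effect size Cohen's d (noncentrality
#' `d * sqrt(n)` against the two-sided alpha critical value), or the
#' single-degree-of-freedom within-subject F contrast with effect size partial
#' eta squared (noncentrality `n * f^2`, `f^2 = eta / (1 - eta)`, df 1 and
#' n - 1).
#'
#' @param test `"paired_t"` or `"within_F"`.
#' @param effect Cohen's d (`paired_t`) or partial eta squared (`within_F`),
#'   >= 0 (and < 1 for eta squared).
#' @param n number of subjects (>= 2).
#' @param alpha significance level.
#' @param two_sided for `paired_t`, whether the test is two-sided.
#' @return power in `[0, 1]`.
#' @export
power_within <- function(test = c("paired_t", "within_F"), effect, n,
                         alpha = 0.05, two_sided = TRUE) {
  test <- match.arg(test)
  if (n < 2L) stopf("n must be >= 2")
  if (effect < 0) stopf("effect must be >= 0")
  if (test == "paired_t") {
    ncp <- effect * sqrt(n)
    df <- n - 1
    if (two_sided) {
      crit <- stats::qt(1 - alpha / 2, df)
      stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
        stats::pt(-crit, df, ncp = ncp)
    } else {
      crit <- stats::qt(1 - alpha, df)
      stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
    }
  } else {
    if (effect >= 1) stopf("partial eta squared must be < 1")
    f2 <- effect / (1 - effect)
    crit <- stats::qf(1 - alpha, 1, n - 1)
    stats::pf(crit, 1, n - 1, ncp = n * f2, lower.tail = FALSE)
  }
}
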