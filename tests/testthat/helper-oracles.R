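# Independent brute-force oracles used to check the package's statistics.
# These deliberately re-derive each quantity from first principles rather than
# calling the implementation under test.

# Benjamini-Hochberg step-up adjusted p values: p_(i) * m / i, cumulative
# minimum from the largest p downward, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Closed-form simple linear regression.
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# One-sample t statistic and two-sided p.
t_oracle <- function(x) {
  n <- length(x)
  t <- mean(x) / (sd(x) / sqrt(n))
  c(t = t, p = 2 * pt(abs(t), n - 1, lower.tail = FALSE))
}

# Box/Greenhouse-Geisser epsilon via the classical sums formula.
box_eps_oracle <- function(S) {
  k <- nrow(S)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  rbar <- rowMeans(S)
  num <- k^2 * (dbar - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rbar^2) + k^2 * sbar^2)
  num / den
}

# Cousineau-Morey within-subject SEs written out longhand.
ws_se_oracle <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  cen <- sweep(x, 1, rowMeans(x)) + mean(x)
  sds <- apply(cen, 2, sd)
  sds * sqrt(k / (k - 1)) / sqrt(n)
}

# Within-subject sums of squares via stats::aov with an Error() stratum.
aov_ss_oracle <- function(df) {
  fit <- summary(stats::aov(y ~ A * B + Error(s / (A * B)), data = df))
  get_ss <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "Sum Sq"]
  }
  list(A = get_ss("Error: s:A", "A"), A_err = get_ss("Error: s:A", "Residuals"),
       B = get_ss("Error: s:B", "B"), B_err = get_ss("Error: s:B", "Residuals"),
       AB = get_ss("Error: s:A:B", "A:B"),
       AB_err = get_ss("Error: s:A:B", "Residuals"))
}

# A tiny flanker-like trial table built by hand (no simulator involved).
manual_table <- function(rts_c, rts_i, subject = 1L, soa = 0L) {
  n <- length(rts_c) + length(rts_i)
  data.frame(
    subject_id = subject, experiment = "EXP1", block_index = 1L,
    block_condition = "N/A", trial_index = seq_len(n), is_practice = FALSE,
    congruency = rep(c("CONGRUENT", "INCONGRUENT"),
                     c(length(rts_c), length(rts_i))),
    target_direction = "LEFT", soa_ms = soa, t_delta_ms = NA_integer_,
    location = "FIXED_CENTER", response = "LEFT",
    rt_ms = as.integer(c(rts_c, rts_i)), stringsAsFactors = FALSE)
}
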