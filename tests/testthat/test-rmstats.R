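test_that("Greenhouse-Geisser epsilon matches oracles and bounds", {
  expect_equal(gg_epsilon(matrix(c(4, 1, 1, 3), 2)), 1) # k = 2 collapses

  # compound symmetry: sphericity holds, epsilon 1
  cs <- matrix(0.4, 5, 5)
  diag(cs) <- 1
  expect_equal(gg_epsilon(cs), 1)

  set.seed(21)
  for (k in c(3, 5, 9)) {
    X <- matrix(rnorm(20 * k), 20, k) %*% matrix(rnorm(k * k), k)
    S <- cov(X)
    eps <- gg_epsilon(S)
    expect_equal(eps, max(min(box_eps_oracle(S), 1), 1 / (k - 1)))
    expect_gte(eps, 1 / (k - 1))
    expect_lte(eps, 1)
  }
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("two-way within ANOVA matches the aov() error-stratum oracle", {
  set.seed(31)
  df <- expand.grid(s = factor(1:6), A = factor(1:3), B = factor(1:4))
  df$y <- rnorm(nrow(df), 500, 40) +
    as.numeric(df$A) * 10 + as.numeric(df$B) * 5 + rnorm(nrow(df), 0, 10)
  out <- rm_anova_2way(df, "y", "s", "A", "B")
  orc <- aov_ss_oracle(df)
  expect_equal(out$ss_effect, c(orc$A, orc$B, orc$AB))
  expect_equal(out$ss_error, c(orc$A_err, orc$B_err, orc$AB_err))
  expect_equal(out$F,
               c(orc$A / 2 / (orc$A_err / 10),
                 orc$B / 3 / (orc$B_err / 15),
                 orc$AB / 6 / (orc$AB_err / 30)))
  expect_equal(out$partial_eta_sq,
               out$ss_effect / (out$ss_effect + out$ss_error))
  expect_equal(out$df1_adj, out$epsilon * out$df1)
  # GG-adjusted p is never smaller than the unadjusted p when F >= 1 (for
  # F < 1 shrinking both df can reduce the tail probability, so the usual
  # "adjustment is conservative" statement only applies to F >= 1)
  p_raw <- pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  big <- out$F >= 1
  expect_true(all(out$p[big] >= p_raw[big] - 1e-12))
})

test_that("within-subject sums of squares are conserved", {
  set.seed(32)
  df <- expand.grid(s = factor(1:8), A = factor(1:5), B = factor(1:2))
  df$y <- rnorm(nrow(df), 0, 1)
  out <- rm_anova_2way(df, "y", "s", "A", "B")
  total <- sum((df$y - mean(df$y))^2)
  parts <- sum(out$ss_effect) + sum(out$ss_error) + attr(out, "ss_subject")
  expect_equal(parts, total, tolerance = 1e-8)
})

test_that("a 2x2 within design reduces to paired t tests: F equals t^2", {
  set.seed(33)
  df <- expand.grid(s = factor(1:10), A = factor(1:2), B = factor(1:2))
  df$y <- rnorm(nrow(df), 450, 60)
  out <- rm_anova_2way(df, "y", "s", "A", "B")

  wide <- tapply(df$y, list(df$s, interaction(df$A, df$B)), mean)
  t_A <- t.test(rowMeans(wide[, c("1.1", "1.2")]),
                rowMeans(wide[, c("2.1", "2.2")]), paired = TRUE)$statistic
  t_B <- t.test(rowMeans(wide[, c("1.1", "2.1")]),
                rowMeans(wide[, c("1.2", "2.2")]), paired = TRUE)$statistic
  t_AB <- t.test((wide[, "1.1"] - wide[, "2.1"]) -
                   (wide[, "1.2"] - wide[, "2.2"]))$statistic
  expect_equal(out$F, unname(c(t_A^2, t_B^2, t_AB^2)), tolerance = 1e-8)
  expect_equal(out$epsilon, rep(1, 3)) # all single-df effects

  flat <- df
  flat$y <- 7
  out0 <- rm_anova_2way(flat, "y", "s", "A", "B")
  expect_equal(out0$F, rep(0, 3))
})

test_that("missing cells and tiny samples are rejected", {
  df <- expand.grid(s = factor(1:4), A = factor(1:2), B = factor(1:2))
  df$y <- rnorm(16)
  expect_error(rm_anova_2way(df[-1, ], "y", "s", "A", "B"), "complete")
  expect_error(rm_anova_2way(df[df$s == 1, ], "y", "s", "A", "B"),
               ">= 2 subjects")
})

test_that("simple effects match a constructed paired-t oracle", {
  fce <- data.frame(subject_id = rep(1:3, 2),
                    condition = rep(c("c1", "c2"), each = 3),
                    fce_rt_ms = c(10, 20, 30, 10, 20, 30),
                    fce_er = 0)
  out <- simple_effects(fce)
  orc <- t_oracle(c(10, 20, 30))
  expect_equal(out$congruency$t, rep(unname(orc["t"]), 2))
  expect_equal(out$congruency$p, rep(unname(orc["p"]), 2))
  # identical conditions: pairwise contrast is exactly zero
  expect_equal(out$pairwise$estimate, 0)
  expect_equal(out$pairwise$t, 0)

  fce$fce_rt_ms[4:6] <- c(25, 30, 50)
  two <- simple_effects(fce)
  d <- c(25, 30, 50) - c(10, 20, 30)
  expect_equal(two$pairwise$estimate, mean(d))
  expect_equal(two$pairwise$t, unname(t_oracle(d)["t"]))

  # one-sided p is half the two-sided p in the hypothesized direction
  one <- simple_effects(fce, alternative = "greater")
  expect_equal(one$congruency$p, two$congruency$p / 2)
})

test_that("identical same/diff distributions give a null carry-over effect", {
  summaries <- expand.grid(subject_id = 1:4,
                           condition = c("VariableSame", "VariableDiff"),
                           congruency = c("CONGRUENT", "INCONGRUENT"),
                           stringsAsFactors = FALSE)
  summaries$median_rt_ms <- 450 + 10 * summaries$subject_id +
    40 * (summaries$congruency == "INCONGRUENT")
  out <- carryover_contrast(summaries)
  expect_equal(out$carryover_congruent_ms, 0)
  expect_equal(out$difference_ms, 0)
  expect_equal(out$t, 0)

  # a subject without a same-location cell is dropped with a warning
  broken <- summaries[-1, ]
  expect_warning(out2 <- carryover_contrast(broken), "excluded 1 subject")
  expect_equal(out2$n, 3)
})

test_that("power computations hit the published bounds and behave", {
  expect_equal(power_within("paired_t", 0, 30), 0.05, tolerance = 1e-10)
  expect_gt(power_within("paired_t", 0.93, 23), 0.95)
  expect_gt(power_within("within_F", 0.61, 40), 0.95)

  # monotone in n and in effect size
  ns <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(sapply(ns, function(n)
    power_within("paired_t", 0.5, n))) > 0))
  es <- seq(0, 1.5, 0.25)
  expect_true(all(diff(sapply(es, function(d)
    power_within("paired_t", d, 20))) > 0))
  expect_true(all(diff(sapply(seq(0.05, 0.8, 0.15), function(e)
    power_within("within_F", e, 20))) > 0))
  # continuity at zero effect
  expect_equal(power_within("paired_t", 1e-9, 20),
               power_within("paired_t", 0, 20), tolerance = 1e-6)
  expect_error(power_within("paired_t", 0.5, 1), ">= 2")
})

test_that("carry-over CI attains nominal coverage under a null simulation", {
  # scaled-down null world (no congruency-specific carry-over): 4 blocks,
  # 8 subjects, 200 seeded replicates; the 95% CI should cover 0 ~95% of
  # the time
  d <- build_exp3("ABBA", seed = 12)
  d <- d[d$block_index <= 4, ]
  params <- gen_params(
    "EXP3",
    data.frame(condition = c("FIXED", "VARIABLE"), delta0_ms = c(40, 55),
               delta1_ms = 0, e_congruent = 0.03, e_incongruent = 0.10),
    kappa_rt_ms = 10, kappa_fce_ms = 0)
  hits <- 0L
  for (r in 1:200) {
    tab <- label_carryover(classify_trials(
      simulate_experiment(d, 8, params, seed = 20000 + r)))
    co <- suppressWarnings(carryover_contrast(summarize_conditions(tab)))
    if (co$ci_lower <= 0 && co$ci_upper >= 0) hits <- hits + 1L
  }
  expect_gte(hits, 180) # binomial(200, .95): 190 +- 3.1
  expect_lte(hits, 199)
})
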