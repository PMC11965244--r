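test_that("percentile estimator interpolates and stays nondecreasing", {
  expect_equal(rt_percentiles(rep(400, 30)), rep(400, 9))
  # linear-interpolation estimator on 1..100: 10th percentile is 10.9
  q <- rt_percentiles(1:100)
  expect_equal(q[1], 10.9)
  expect_equal(q, unname(quantile(1:100, seq(0.1, 0.9, 0.1), type = 7)))

  set.seed(4)
  for (i in 1:20) {
    expect_true(all(diff(rt_percentiles(rlnorm(50, 6, 0.3))) >= 0))
  }
  expect_error(rt_percentiles(1:5), "at least 10")
})

test_that("per-subject delta plots difference and average the percentiles", {
  rts <- c(310, 355, 400, 430, 470, 520, 580, 640, 700, 820)
  same <- subject_delta(rts, rts)
  expect_equal(same$fce_rt_ms, rep(0, 9))
  expect_equal(same$bin_rt_ms, rt_percentiles(rts))

  shifted <- subject_delta(rts, rts + 50)
  expect_equal(shifted$fce_rt_ms, rep(50, 9))
  expect_equal(shifted$bin_rt_ms, rt_percentiles(rts) + 25)
})

test_that("effects at each bin are invariant under a common shift only", {
  rts_c <- qexgauss(seq(0.05, 0.95, length.out = 40), 400, 50, 100)
  rts_i <- rts_c + 40
  base <- subject_delta(rts_c, rts_i)$fce_rt_ms
  shift <- subject_delta(rts_c + 120, rts_i + 120)$fce_rt_ms
  expect_equal(shift, base)
  scaled <- subject_delta(rts_c * 1.5, rts_i * 1.5)$fce_rt_ms
  expect_false(isTRUE(all.equal(scaled, base)))
})

test_that("slope fit matches the closed-form OLS oracle", {
  dp <- subject_delta(1:20 * 20 + 100, 1:20 * 20 + 130)
  flat <- fit_slope(dp)
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_equal(flat$intercept_ms, 30)

  dp$fce_rt_ms <- 2 * dp$bin_rt_ms
  prop <- fit_slope(dp)
  expect_equal(prop$slope, 2)
  expect_equal(prop$intercept_ms, 0, tolerance = 1e-9)

  set.seed(8)
  dp$bin_rt_ms <- sort(runif(9, 300, 700))
  dp$fce_rt_ms <- rnorm(9, 30, 15)
  fit <- fit_slope(dp)
  orc <- ols_oracle(dp$bin_rt_ms, dp$fce_rt_ms)
  expect_equal(fit$slope, unname(orc["slope"]))
  expect_equal(fit$intercept_ms, unname(orc["intercept"]))

  dp$bin_rt_ms <- rep(500, 9)
  degen <- fit_slope(dp)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$slope))
})

test_that("group slope test matches t and Benjamini-Hochberg oracles", {
  slopes <- data.frame(
    subject_id = rep(1:3, 2),
    condition = rep(c("a", "b"), each = 3),
    slope = c(0, 0, 0, 1, 2, 3))
  out <- group_slope_test(slopes)
  expect_equal(out$t[out$condition == "a"], 0)
  expect_equal(out$p_bh[out$condition == "a"], 1)
  orc <- t_oracle(c(1, 2, 3))
  expect_equal(out$t[out$condition == "b"], unname(orc["t"]))
  expect_equal(out$t[out$condition == "b"], 2 * sqrt(3))
  expect_equal(out$cohens_d[out$condition == "b"], 2)

  # BH step-up on a nine-comparison family with evenly spaced raw p values
  p <- seq(0.01, 0.09, 0.01)
  expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  expect_equal(p.adjust(p, "BH"), rep(0.09, 9))

  set.seed(3)
  many <- data.frame(subject_id = rep(1:8, 9),
                     condition = rep(letters[1:9], each = 8),
                     slope = rnorm(72, 0.05, 0.2))
  res <- group_slope_test(many)
  expect_equal(res$p_bh, bh_oracle(res$p))
  o <- order(res$p)
  expect_true(all(diff(res$p_bh[o]) >= -1e-12))
  expect_true(all(res$p_bh >= res$p))
})

test_that("group curves average subject curves; mirrored effects cancel", {
  bins <- data.frame(subject_id = 1, condition = "x",
                     percentile = seq(10, 90, 10),
                     bin_rt_ms = seq(300, 700, 50),
                     fce_rt_ms = rnorm(9))
  g1 <- group_delta_plot(bins)
  expect_equal(g1$bin_rt_ms, bins$bin_rt_ms)
  expect_equal(g1$fce_rt_ms, bins$fce_rt_ms)

  mirror <- bins
  mirror$subject_id <- 2
  mirror$fce_rt_ms <- -bins$fce_rt_ms
  g2 <- group_delta_plot(rbind(bins, mirror))
  expect_equal(g2$fce_rt_ms, rep(0, 9))
})

test_that("polynomial contrasts isolate linear and quadratic trends", {
  mk_bins <- function(fce_fun) {
    do.call(rbind, lapply(1:6, function(s) {
      data.frame(subject_id = s, condition = "x",
                 percentile = seq(10, 90, 10),
                 bin_rt_ms = seq(300, 700, 50),
                 fce_rt_ms = fce_fun(1:9) + s)
    }))
  }
  lin <- polynomial_contrasts(mk_bins(function(b) 3 * b))
  expect_equal(lin$estimate[lin$trend == "quadratic"], 0, tolerance = 1e-10)
  expect_gt(lin$estimate[lin$trend == "linear"], 0)

  quad <- polynomial_contrasts(mk_bins(function(b) (b - 5)^2))
  expect_equal(quad$estimate[quad$trend == "linear"], 0, tolerance = 1e-10)
  expect_gt(quad$estimate[quad$trend == "quadratic"], 0)

  # random data: estimates equal the explicit dot-product oracle
  set.seed(9)
  y <- rnorm(9, 20, 10)
  bins <- do.call(rbind, lapply(1:2, function(s) {
    data.frame(subject_id = s, condition = "x",
               percentile = seq(10, 90, 10), bin_rt_ms = 1:9,
               fce_rt_ms = y + s)
  }))
  out <- polynomial_contrasts(bins)
  cp <- contr.poly(9)
  expect_equal(out$estimate[out$trend == "linear"], sum(cp[, 1] * y),
               tolerance = 1e-10)
  expect_equal(out$estimate[out$trend == "quadratic"], sum(cp[, 2] * y),
               tolerance = 1e-10)
})

test_that("delta_plots excludes sparse cells with a warning", {
  tab <- classify_trials(manual_table(rep(300:350, 2), rep(400, 5)))
  expect_warning(dp <- delta_plots(tab), "below min_trials")
  expect_null(dp$slopes)
})
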