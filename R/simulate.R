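# Synthetic trial-level response generator.
#
# Every analysis stage in the package is exercised against data from this
# module, so its parameters are the pipeline's ground truth: a per-subject
# ex-Gaussian base RT, a per-condition interference offset (mean congruency
# effect at the median) and gradient (change in the effect from the fastest to
# the slowest quantile, which sets the delta-plot slope sign), per-condition
# error probabilities, and location carry-over increments.
#
# Interference is quantile-coupled: the incongruent RT reuses the uniform draw
# u of its counterfactual congruent RT, T_I = Q(u) + delta0 + delta1*(u - 1/2).
# This is a simulation device that makes the delta-plot slope directly
# controllable, not a claim about processing mechanisms.

#' Construct a generator parameter set
#'
#' @param experiment one of "EXP1", "EXP2A", "EXP2B", "EXP3".
#' @param conditions data frame with columns `condition` (character key:
#'   the SOA for EXP1, the contrast-change time or "none" for EXP2A/B,
#'   "FIXED"/"VARIABLE" for EXP3), `delta0_ms`, `delta1_ms`, `e_congruent`,
#'   `e_incongruent`. Must cover every design cell.
#' @param population list of population means/SDs for the subject-level
#'   ex-Gaussian base RT: `mu_mean`, `mu_sd`, `sigma_mean`, `sigma_sd`,
#'   `tau_mean`, `tau_sd` (ms).
#' @param kappa_rt_ms RT increment on Variable-Diff trials (EXP3, ms).
#' @param kappa_fce_ms additional incongruent-only RT increment on
#'   Variable-Diff trials (EXP3, ms); this is the congruency-specific
#'   carry-over effect the analysis should recover.
#' @param premature_rate probability in `[0, 1)` that a flanker-first (negative
#'   SOA) trial draws a premature response landing before target onset.
#' @param timeout_ms response deadline relative to target onset; `NULL` uses
#'   the experiment's own deadline (1 s from stimulus offset for EXP1/EXP2,
#'   1.25 s from onset for EXP3). `Inf` disables timeouts.
#' @return validated parameter list of class `gen_params`.
#' @export
gen_params <- function(experiment,
                       conditions,
                       population = list(mu_mean = 400, mu_sd = 30,
                                         sigma_mean = 50, sigma_sd = 10,
                                         tau_mean = 100, tau_sd = 20),
                       kappa_rt_ms = 0,
                       kappa_fce_ms = 0,
                       premature_rate = 0,
                       timeout_ms = NULL) {
  experiment <- match.arg(experiment, c("EXP1", "EXP2A", "EXP2B", "EXP3"))
  need <- c("condition", "delta0_ms", "delta1_ms", "e_congruent",
            "e_incongruent")
  if (!all(need %in% names(conditions))) {
    stopf("conditions must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(conditions$e_congruent < 0 | conditions$e_congruent > 1) ||
      any(conditions$e_incongruent < 0 | conditions$e_incongruent > 1)) {
    stopf("error probabilities must lie in [0, 1]")
  }
  if (premature_rate < 0 || premature_rate >= 1) {
    stopf("premature_rate must lie in [0, 1)")
  }
  with(population, stopifnot(mu_mean > 0, sigma_mean > 0, tau_mean > 0,
                             mu_sd >= 0, sigma_sd >= 0, tau_sd >= 0))
  structure(list(experiment = experiment,
                 conditions = conditions,
                 population = population,
                 kappa_rt_ms = kappa_rt_ms,
                 kappa_fce_ms = kappa_fce_ms,
                 premature_rate = premature_rate,
                 timeout_ms = timeout_ms),
            class = "gen_params")
}

#' Generator presets emulating the published qualitative result pattern
#'
#' Returns a [gen_params()] configuration whose large-sample behavior mirrors
#' each experiment's headline findings: for the SOA experiment, interference
#' peaks when flankers lead the target by 50-100 ms, vanishes once flankers
#' trail by 100 ms or more, and the interference gradient is negative at SOAs
#' -200/-100 and positive at +30/+50/+100; for the dynamic-contrast
#' experiments, a roughly constant RT effect (variant A, smaller at the 33-ms
#' change) or an error-rate effect that shrinks as the contrast change is
#' delayed plus negative gradients at the 50/67-ms changes (variant B); for
#' the location-uncertainty experiment, RT interference of about 43 ms in
#' Fixed blocks and 57 ms on Variable-Same trials, with carry-over increments
#' that raise Variable-Diff interference by a further 21 ms.
#'
#' @param experiment one of "EXP1", "EXP2A", "EXP2B", "EXP3".
#' @return a `gen_params` object.
#' @export
preset_paper_like <- function(experiment = c("EXP1", "EXP2A", "EXP2B",
                                             "EXP3")) {
  experiment <- match.arg(experiment)
  if (experiment == "EXP1") {
    cond <- data.frame(
      condition = as.character(SOA_LEVELS_MS),
      delta0_ms = c(30, 45, 65, 65, 50, 35, 25, 0, 0),
      delta1_ms = c(0, -60, -60, 0, 0, 60, 70, 50, 0),
      e_congruent = rep(0.03, 9),
      e_incongruent = c(0.11, 0.15, 0.23, 0.23, 0.13, 0.09, 0.07, 0.045,
                        0.03),
      stringsAsFactors = FALSE)
    return(gen_params("EXP1", cond, premature_rate = 0.02))
  }
  if (experiment == "EXP2A") {
    cond <- data.frame(
      condition = c("33", "50", "67", "83", "none"),
      delta0_ms = c(40, 55, 55, 55, 55),
      delta1_ms = rep(0, 5),
      e_congruent = rep(0.03, 5),
      e_incongruent = rep(0.09, 5),
      stringsAsFactors = FALSE)
    return(gen_params("EXP2A", cond))
  }
  if (experiment == "EXP2B") {
    cond <- data.frame(
      condition = c("33", "50", "67", "83", "none"),
      delta0_ms = rep(55, 5),
      delta1_ms = c(0, -35, -40, 0, 0),
      e_congruent = c(0.040, 0.035, 0.030, 0.030, 0.030),
      e_incongruent = c(0.180, 0.150, 0.120, 0.100, 0.080),
      stringsAsFactors = FALSE)
    return(gen_params("EXP2B", cond))
  }
  cond <- data.frame(
    condition = c("FIXED", "VARIABLE"),
    delta0_ms = c(43, 57),
    delta1_ms = c(20, 20),
    e_congruent = c(0.035, 0.040),
    e_incongruent = c(0.082, 0.107),
    stringsAsFactors = FALSE)
  gen_params("EXP3", cond, kappa_rt_ms = 15, kappa_fce_ms = 21)
}

# Response deadline in ms relative to target onset. EXP1/EXP2: 1 s from
# stimulus offset (the array stays up 100 ms past the scheduled change/SOA);
# EXP3: 1.25 s from stimulus onset.
response_deadline <- function(experiment, soa_ms) {
  switch(experiment,
    EXP1 = pmax(soa_ms, 0L) + 100 + 1000,
    EXP2A = ,
    EXP2B = 100 + 1000,
    EXP3 = rep(1250, length(soa_ms)),
    stopf("unknown experiment '%s'", experiment))
}

condition_key_for_params <- function(design) {
  exp <- design$experiment
  out <- rep(NA_character_, nrow(design))
  i1 <- exp == "EXP1"
  out[i1] <- as.character(design$soa_ms[i1])
  i2 <- exp %in% c("EXP2A", "EXP2B")
  out[i2] <- ifelse(is.na(design$t_delta_ms[i2]), "none",
                    as.character(design$t_delta_ms[i2]))
  i3 <- exp == "EXP3"
  out[i3] <- design$block_condition[i3]
  out
}

# Variable-Diff indicator for carry-over increments: a Variable-block trial
# whose location differs from the immediately preceding trial in its block.
variable_diff_flag <- function(design) {
  prev_loc <- c(NA_character_, design$location[-nrow(design)])
  first <- !duplicated(design[, c("block_index", "is_practice")])
  design$experiment == "EXP3" & design$block_condition == "VARIABLE" &
    !first & design$location != prev_loc
}

opposite_dir <- function(d) ifelse(d == "LEFT", "RIGHT", "LEFT")

# Vectorized core: simulate one subject's responses over a design, given that
# subject's ex-Gaussian parameters. Assumes the RNG is already seeded.
simulate_subject_rows <- function(design, subj, mu, sigma, tau, params) {
  n <- nrow(design)
  key <- condition_key_for_params(design)
  idx <- match(key, params$conditions$condition)
  if (anyNA(idx)) {
    stopf("no generator parameters for condition(s): %s",
          paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  cond <- params$conditions[idx, , drop = FALSE]
  incong <- design$congruency == "INCONGRUENT"

  u <- stats::runif(n)
  rt <- qexgauss(u, mu, sigma, tau)
  rt[incong] <- rt[incong] + cond$delta0_ms[incong] +
    cond$delta1_ms[incong] * (u[incong] - 0.5)

  vdiff <- variable_diff_flag(design)
  rt[vdiff] <- rt[vdiff] + params$kappa_rt_ms
  rt[vdiff & incong] <- rt[vdiff & incong] + params$kappa_fce_ms

  e <- ifelse(incong, cond$e_incongruent, cond$e_congruent)
  err <- stats::runif(n) < e
  response <- ifelse(err, opposite_dir(design$target_direction),
                     design$target_direction)

  # premature responses land before target onset on flanker-first trials
  pre <- design$experiment == "EXP1" & !is.na(design$soa_ms) &
    design$soa_ms < 0 & stats::runif(n) < params$premature_rate
  if (any(pre)) {
    rt[pre] <- stats::runif(sum(pre), design$soa_ms[pre], 0)
    response[pre] <- sample(DIRECTION_LEVELS, sum(pre), replace = TRUE)
  }

  rt <- floor(rt)
  deadline <- params$timeout_ms %||%
    response_deadline(design$experiment[1L], design$soa_ms)
  late <- rt > deadline
  response[late] <- "NONE"
  rt[late] <- NA_real_

  cbind(data.frame(subject_id = subj),
        design,
        data.frame(response = response, rt_ms = as.integer(rt),
                   stringsAsFactors = FALSE))
}

#' Draw one subject's ex-Gaussian base-RT parameters
#'
#' Normal population draws clipped to sensible floors (mu >= 150 ms,
#' sigma/tau >= 10 ms). Assumes the RNG is seeded by the caller.
#'
#' @param population population list as in [gen_params()].
#' @return list with `mu`, `sigma`, `tau`.
#' @export
draw_subject_params <- function(population) {
  list(mu = max(stats::rnorm(1, population$mu_mean, population$mu_sd), 150),
       sigma = max(stats::rnorm(1, population$sigma_mean,
                                population$sigma_sd), 10),
       tau = max(stats::rnorm(1, population$tau_mean, population$tau_sd), 10))
}

#' Simulate responses for one trial
#'
#' Single-trial convenience wrapper around the vectorized generator; the
#' block-sequence context enters through `prev_location`.
#'
#' @param spec one-row trial-spec data frame.
#' @param params a [gen_params()] object.
#' @param subject_params list with `mu`, `sigma`, `tau` (ms), e.g. from
#'   [draw_subject_params()].
#' @param prev_location location of the immediately preceding trial in the
#'   same block, or `NA` if this is the block's first trial.
#' @param subject_id subject identifier recorded in the output row.
#' @return one trial-record row.
#' @export
simulate_trial <- function(spec, params, subject_params,
                           prev_location = NA_character_, subject_id = 1L) {
  stopifnot(nrow(spec) == 1L)
  if (!is.na(prev_location) && spec$experiment == "EXP3" &&
      spec$block_condition == "VARIABLE" && spec$trial_index > 1L) {
    # splice a phantom predecessor so the vectorized carry-over rule applies
    ctx <- spec
    ctx$trial_index <- spec$trial_index - 1L
    ctx$location <- prev_location
    rows <- simulate_subject_rows(rbind(ctx, spec), subject_id,
                                  subject_params$mu, subject_params$sigma,
                                  subject_params$tau, params)
    return(rows[2L, , drop = FALSE])
  }
  simulate_subject_rows(spec, subject_id, subject_params$mu,
                        subject_params$sigma, subject_params$tau, params)
}

#' Simulate a full experiment
#'
#' Each subject receives independent ex-Gaussian base-RT parameters drawn from
#' the population configuration and an independently randomized copy of the
#' responses over the (shared) design. All randomness derives from `seed`;
#' the same seed reproduces the identical trial table.
#'
#' @param design trial-spec data frame from [build_exp1()], [build_exp2()] or
#'   [build_exp3()].
#' @param n_subjects number of subjects (>= 1).
#' @param params a [gen_params()] object (see [preset_paper_like()]).
#' @param seed integer master seed.
#' @return trial table: one trial-record row per subject x design row, in the
#'   schema accepted by [read_trials()]/[validate_trials()].
#' @export
simulate_experiment <- function(design, n_subjects, params, seed = 1L) {
  stopifnot(inherits(params, "gen_params"))
  if (nrow(design) == 0L) stopf("empty design")
  if (n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (any(design$experiment != params$experiment)) {
    stopf("design experiment does not match params experiment '%s'",
          params$experiment)
  }
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    out[[s]] <- with_seed(derive_seed(seed, s), {
      sp <- draw_subject_params(params$population)
      simulate_subject_rows(design, s, sp$mu, sp$sigma, sp$tau, params)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
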