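# Trial-schedule construction for the three flanker experiments.
#
# All schedules are returned as "trial spec" data frames: one row per
# presented trial, experimental and practice alike, in presentation order.
# Randomization is per block, seeded from (master seed, block stream), so the
# same seed always reproduces the same schedule and individual blocks are
# stable under partial rebuilds.

#' Stimulus onset asynchronies of the timing experiment (ms)
#'
#' Negative values: flankers precede the target; positive: flankers follow.
#' @export
SOA_LEVELS_MS <- c(-400L, -200L, -100L, -50L, 0L, 30L, 50L, 100L, 200L)

#' Contrast-change times of the dynamic-contrast experiments (ms after onset)
#'
#' The constant-contrast control condition carries no change time and is coded
#' as `NA` in trial tables (printed as "none" in condition labels).
#' @export
TDELTA_LEVELS_MS <- c(33L, 50L, 67L, 83L)

CONGRUENCY_LEVELS <- c("CONGRUENT", "INCONGRUENT")
DIRECTION_LEVELS <- c("LEFT", "RIGHT")
LOCATION_LEVELS <- c("FIXED_CENTER", "V1", "V2", "V3", "V4")

trialspec_cols <- c("experiment", "block_index", "block_condition",
                    "trial_index", "is_practice", "congruency",
                    "target_direction", "soa_ms", "t_delta_ms", "location")

new_block <- function(experiment, block_index, block_condition, is_practice,
                      congruency, target_direction, soa_ms = NA_integer_,
                      t_delta_ms = NA_integer_, location = "FIXED_CENTER") {
  n <- length(congruency)
  data.frame(
    experiment = rep(experiment, n),
    block_index = rep(as.integer(block_index), n),
    block_condition = rep(block_condition, n),
    trial_index = seq_len(n),
    is_practice = rep(is_practice, n),
    congruency = congruency,
    target_direction = target_direction,
    soa_ms = as.integer(rep_len(soa_ms, n)),
    t_delta_ms = as.integer(rep_len(t_delta_ms, n)),
    location = rep_len(location, n),
    stringsAsFactors = FALSE
  )
}

shuffle_rows <- function(df, seed) {
  out <- with_seed(seed, df[sample.int(nrow(df)), , drop = FALSE])
  rownames(out) <- NULL
  out
}

rbind_clean <- function(blocks) {
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Build the trial schedule of the SOA-manipulation experiment
#'
#' Eight experimental blocks of 108 trials. Within each block, the four
#' congruency x target-direction configurations appear three times at each of
#' the nine SOAs, in seeded random order (864 experimental trials). A 36-trial
#' practice block precedes them, containing every congruency x direction x SOA
#' cell exactly once.
#'
#' @param seed integer master seed for the block-wise shuffles.
#' @return data frame of trial specs in presentation order; practice rows are
#'   flagged with `is_practice = TRUE` (block 1), experimental blocks are
#'   numbered 1..8 with `is_practice = FALSE`.
#' @export
build_exp1 <- function(seed = 1L) {
  cells <- expand.grid(congruency = CONGRUENCY_LEVELS,
                       target_direction = DIRECTION_LEVELS,
                       soa_ms = SOA_LEVELS_MS,
                       stringsAsFactors = FALSE)
  practice <- shuffle_rows(cells, derive_seed(seed, 0L))
  blocks <- vector("list", 9L)
  blocks[[1L]] <- new_block("EXP1", 1L, "N/A", TRUE,
                            practice$congruency, practice$target_direction,
                            soa_ms = practice$soa_ms)
  reps <- cells[rep(seq_len(nrow(cells)), times = 3L), , drop = FALSE]
  for (b in seq_len(8L)) {
    sh <- shuffle_rows(reps, derive_seed(seed, b))
    blocks[[b + 1L]] <- new_block("EXP1", b, "N/A", FALSE,
                                  sh$congruency, sh$target_direction,
                                  soa_ms = sh$soa_ms)
  }
  rbind_clean(blocks)
}

#' Build the trial schedule of a dynamic-contrast experiment
#'
#' Twelve experimental blocks of 80 trials: each congruency x direction
#' configuration appears four times per block at each of the five
#' contrast-change conditions (33/50/67/83 ms or constant), for 96 trials per
#' change-time x congruency cell overall. Stimulus location is drawn per trial
#' from the four diagonal offsets. Two practice blocks precede them: 16
#' constant-contrast trials, then 36 dynamic trials (18 at 50 ms and 18 at
#' 67 ms; the extreme change times are excluded from practice).
#'
#' @param variant "A" (flanker contrast boost only) or "B" (flanker boost plus
#'   target contrast reduction); the schedules are identical in structure.
#' @param seed integer master seed.
#' @return data frame of trial specs in presentation order.
#' @export
build_exp2 <- function(variant = c("A", "B"), seed = 1L) {
  variant <- match.arg(variant)
  experiment <- paste0("EXP2", variant)
  vloc <- c("V1", "V2", "V3", "V4")

  # practice 1: 16 constant-contrast trials (4 configurations x 4)
  p1 <- expand.grid(congruency = CONGRUENCY_LEVELS,
                    target_direction = DIRECTION_LEVELS,
                    rep = 1:4, stringsAsFactors = FALSE)
  p1 <- shuffle_rows(p1, derive_seed(seed, 100L))
  # practice 2: 36 dynamic trials, 18 each at 50 and 67 ms
  p2 <- expand.grid(congruency = CONGRUENCY_LEVELS,
                    target_direction = DIRECTION_LEVELS,
                    stringsAsFactors = FALSE)
  p2 <- p2[rep(seq_len(4L), length.out = 18L), , drop = FALSE]
  p2 <- rbind(cbind(p2, t_delta_ms = 50L), cbind(p2, t_delta_ms = 67L))
  p2 <- shuffle_rows(p2, derive_seed(seed, 101L))

  blocks <- vector("list", 14L)
  blocks[[1L]] <- with_seed(derive_seed(seed, 102L),
    new_block(experiment, 1L, "N/A", TRUE, p1$congruency,
              p1$target_direction, t_delta_ms = NA_integer_,
              location = sample(vloc, nrow(p1), replace = TRUE)))
  blocks[[2L]] <- with_seed(derive_seed(seed, 103L),
    new_block(experiment, 2L, "N/A", TRUE, p2$congruency,
              p2$target_direction, t_delta_ms = p2$t_delta_ms,
              location = sample(vloc, nrow(p2), replace = TRUE)))

  cells <- expand.grid(congruency = CONGRUENCY_LEVELS,
                       target_direction = DIRECTION_LEVELS,
                       t_delta = c(TDELTA_LEVELS_MS, NA_integer_),
                       rep = 1:4, stringsAsFactors = FALSE)
  for (b in seq_len(12L)) {
    sh <- shuffle_rows(cells, derive_seed(seed, b))
    blocks[[b + 2L]] <- with_seed(derive_seed(seed, 200L + b),
      new_block(experiment, b, "N/A", FALSE, sh$congruency,
                sh$target_direction, t_delta_ms = sh$t_delta,
                location = sample(vloc, nrow(sh), replace = TRUE)))
  }
  rbind_clean(blocks)
}

#' Build the trial schedule of the location-uncertainty experiment
#'
#' Twelve blocks of 80 trials alternating between Fixed blocks (every stimulus
#' centered at fixation) and Variable blocks (stimulus location drawn per
#' trial from four cardinal offsets), arranged as three repetitions of an ABBA
#' or BAAB reverse-counterbalanced order (A = the first block's condition,
#' Fixed for "ABBA", Variable for "BAAB"). This yields 480 trials per location
#' condition. Congruency x direction is exactly balanced (20 trials each)
#' within every block.
#'
#' @param counterbalance "ABBA" or "BAAB".
#' @param seed integer master seed.
#' @param balanced_locations if `TRUE`, each Variable block presents each of
#'   the four locations exactly 20 times (shuffled); the default draws the
#'   location independently and uniformly per trial.
#' @return data frame of trial specs in presentation order.
#' @export
build_exp3 <- function(counterbalance = c("ABBA", "BAAB"), seed = 1L,
                       balanced_locations = FALSE) {
  counterbalance <- match.arg(counterbalance)
  unit <- if (counterbalance == "ABBA") {
    c("FIXED", "VARIABLE", "VARIABLE", "FIXED")
  } else {
    c("VARIABLE", "FIXED", "FIXED", "VARIABLE")
  }
  block_cond <- rep(unit, times = 3L)
  vloc <- c("V1", "V2", "V3", "V4")
  cells <- expand.grid(congruency = CONGRUENCY_LEVELS,
                       target_direction = DIRECTION_LEVELS,
                       rep = 1:20, stringsAsFactors = FALSE)
  blocks <- vector("list", 12L)
  for (b in seq_len(12L)) {
    sh <- shuffle_rows(cells, derive_seed(seed, b))
    if (block_cond[b] == "FIXED") {
      loc <- "FIXED_CENTER"
    } else if (balanced_locations) {
      loc <- with_seed(derive_seed(seed, 300L + b),
                       sample(rep(vloc, each = 20L)))
    } else {
      loc <- with_seed(derive_seed(seed, 300L + b),
                       sample(vloc, nrow(sh), replace = TRUE))
    }
    blocks[[b]] <- new_block("EXP3", b, block_cond[b], FALSE,
                             sh$congruency, sh$target_direction,
                             location = loc)
  }
  rbind_clean(blocks)
}

#' Stimulus eccentricity from horizontal and vertical offsets
#'
#' Euclidean distance (degrees of visual angle) of a stimulus center from
#' fixation, given its offsets along the two axes. The dynamic-contrast
#' experiments displace the array by 0.75 deg on both axes (diagonal), putting
#' the target 1.06 deg from fixation; the location-uncertainty experiment uses
#' single-axis (cardinal) 0.75 deg offsets.
#'
#' @param horizontal_deg,vertical_deg offsets in degrees.
#' @return eccentricity in degrees.
#' @examples
#' stimulus_eccentricity(0.75, 0.75) # ~1.06
#' @export
stimulus_eccentricity <- function(horizontal_deg, vertical_deg) {
  sqrt(horizontal_deg^2 + vertical_deg^2)
}

#' Stimulus contrast (luminance) levels of the dynamic-contrast experiments
#'
#' Low and high arrowhead luminances in cd/m^2; the moderate level, at which
#' every stimulus is initially presented, is their geometric mean.
#'
#' @param low,high luminances in cd/m^2.
#' @return named vector `c(low, moderate, high)`.
#' @examples
#' contrast_levels() # moderate ~106.7
#' @export
contrast_levels <- function(low = 54.3, high = 209.6) {
  c(low = low, moderate = sqrt(low * high), high = high)
}

#' Geometry constants of the dynamic-contrast experiments
#'
#' @return list with the per-axis diagonal offset (degrees) and the resulting
#'   eccentricity of the four possible stimulus locations.
#' @export
exp2_geometry <- function() {
  list(offset_deg = 0.75,
       eccentricity_deg = stimulus_eccentricity(0.75, 0.75))
}
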