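# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' `.Random.seed` afterwards, so library functions never disturb user-level
#' random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stable sub-seed from (master seed, stream index). Lehmer-style
# mixing mod 2^31 - 1; products stay below 2^53 so double arithmetic is exact.
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (abs(as.double(master)) %% m)
  s <- (s * 48271 + as.double(index) * 69621 + 1) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Condition label for each trial row, on the scale the experiment's analyses
# use: SOA for the timing experiment, contrast-change time for the dynamic
# contrast experiments ("none" = constant control), and the location-certainty
# level (Fixed / VariableSame / VariableDiff) for the uncertainty experiment.
condition_of <- function(table) {
  exp <- table$experiment
  out <- rep(NA_character_, nrow(table))
  i1 <- exp == "EXP1"
  out[i1] <- as.character(table$soa_ms[i1])
  i2 <- exp %in% c("EXP2A", "EXP2B")
  out[i2] <- ifelse(is.na(table$t_delta_ms[i2]), "none",
                    as.character(table$t_delta_ms[i2]))
  i3 <- exp == "EXP3"
  if (any(i3)) {
    if (is.null(table$loc_cond)) {
      stopf("EXP3 rows need carry-over labels; run label_carryover() first")
    }
    out[i3] <- as.character(table$loc_cond[i3])
  }
  out
}

condition_levels <- function(experiment) {
  switch(experiment,
    EXP1  = as.character(c(-400, -200, -100, -50, 0, 30, 50, 100, 200)),
    EXP2A = ,
    EXP2B = c("33", "50", "67", "83", "none"),
    EXP3  = c("Fixed", "VariableSame", "VariableDiff"),
    stopf("unknown experiment '%s'", experiment)
  )
}
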