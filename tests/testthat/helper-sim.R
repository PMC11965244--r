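# Minimal single-condition designs and generator configs for focused
# simulator tests (full experiment schedules are exercised elsewhere).

cell_design <- function(soa = 0L, n_per_cell = 100L) {
  n <- 2L * n_per_cell
  data.frame(
    experiment = "EXP1", block_index = 1L, block_condition = "N/A",
    trial_index = seq_len(n), is_practice = FALSE,
    congruency = rep(c("CONGRUENT", "INCONGRUENT"), each = n_per_cell),
    target_direction = rep(c("LEFT", "RIGHT"), n_per_cell),
    soa_ms = as.integer(soa), t_delta_ms = NA_integer_,
    location = "FIXED_CENTER", stringsAsFactors = FALSE)
}

cell_params <- function(soa = 0, delta0 = 0, delta1 = 0, e_c = 0, e_i = 0,
                        premature_rate = 0, timeout_ms = Inf, ...) {
  gen_params("EXP1",
             data.frame(condition = as.character(soa), delta0_ms = delta0,
                        delta1_ms = delta1, e_congruent = e_c,
                        e_incongruent = e_i, stringsAsFactors = FALSE),
             premature_rate = premature_rate, timeout_ms = timeout_ms, ...)
}

# simulate -> classify -> summarize -> congruency effects, in one call
sim_fce <- function(design, n_subjects, params, seed) {
  tab <- classify_trials(simulate_experiment(design, n_subjects, params,
                                             seed = seed))
  compute_fce(summarize_conditions(tab))
}
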