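# Trial classification and carry-over labeling.
#
# RT is referenced to target onset throughout. A response is correct when it
# matches the target direction, arrives inside the response window, and is not
# premature (before target onset). Responses faster than the RT cutoff
# (default 200 ms) are treated as incorrect for all analyses, per the study's
# exclusion rule; the same rule is applied to all three experiments.

#' Classify responses and derive analysis flags
#'
#' Appends four logical/derived columns to a trial table: `premature`
#' (`rt_ms < 0`, i.e. the response landed before target onset), `correct`
#' (response matches the target direction, is not premature and is not faster
#' than `rt_cutoff_ms`), `usable_for_rt` (correct trials entering RT
#' statistics), and keeps missing responses (`response == "NONE"`) incorrect.
#'
#' @param table trial table (schema of [validate_trials()]).
#' @param rt_cutoff_ms responses faster than this (ms from target onset) are
#'   marked incorrect for every analysis; default 200.
#' @return the table with `premature`, `correct`, `usable_for_rt` columns.
#' @export
classify_trials <- function(table, rt_cutoff_ms = 200) {
  bad <- table$response == "NONE" & !is.na(table$rt_ms)
  if (any(bad)) {
    stopf("malformed rows (RT present with response NONE): %s",
          paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  has_rt <- !is.na(table$rt_ms)
  premature <- has_rt & table$rt_ms < 0
  correct <- has_rt & !premature &
    table$response == table$target_direction &
    table$rt_ms >= rt_cutoff_ms
  table$premature <- premature
  table$correct <- correct
  table$usable_for_rt <- correct & has_rt & !is.na(table$rt_ms)
  table
}

#' Label location carry-over conditions (location-uncertainty experiment)
#'
#' Within each block the first trial is labeled `FIRST` and excluded from all
#' analyses. On Variable blocks, a trial whose stimulus location equals that of
#' the immediately preceding trial is `SAME`, otherwise `DIFF` (the preceding
#' trial's correctness is irrelevant). Non-first trials of Fixed blocks are
#' labeled `FIXED` and retained. A `loc_cond` column maps these onto the three
#' analysis levels `Fixed`, `VariableSame`, `VariableDiff` (`NA` for excluded
#' first trials).
#'
#' @param table trial table containing only (or at least) EXP3 rows, ordered by
#'   (subject, block, trial) within EXP3.
#' @return the table with `carryover` and `loc_cond` columns added; non-EXP3
#'   rows get `carryover = "N/A"`.
#' @export
label_carryover <- function(table) {
  carry <- rep("N/A", nrow(table))
  loc_cond <- rep(NA_character_, nrow(table))
  i3 <- which(table$experiment == "EXP3")
  if (length(i3)) {
    sub <- table[i3, , drop = FALSE]
    o <- order(sub$subject_id, sub$block_index, sub$trial_index)
    if (!identical(o, seq_along(i3))) {
      stopf("EXP3 rows must be ordered by (subject, block, trial)")
    }
    first <- !duplicated(sub[, c("subject_id", "block_index")])
    prev_loc <- c(NA_character_, sub$location[-nrow(sub)])
    lab <- ifelse(first, "FIRST",
           ifelse(sub$block_condition == "FIXED", "FIXED",
           ifelse(sub$location == prev_loc, "SAME", "DIFF")))
    carry[i3] <- lab
    loc_cond[i3] <- c(FIRST = NA, FIXED = "Fixed", SAME = "VariableSame",
                      DIFF = "VariableDiff")[lab]
  }
  table$carryover <- carry
  table$loc_cond <- loc_cond
  table
}

#' Per-subject carry-over trial counts
#'
#' @param table a trial table labeled by [label_carryover()].
#' @return data frame with per-subject counts of retained Fixed trials and of
#'   Variable-Same / Variable-Diff / excluded first trials.
#' @export
carryover_counts <- function(table) {
  if (is.null(table$carryover)) stopf("run label_carryover() first")
  sub <- table[table$experiment == "EXP3", , drop = FALSE]
  subj <- sort(unique(sub$subject_id))
  cnt <- function(lab) {
    vapply(subj, function(s) {
      sum(sub$subject_id == s & sub$carryover == lab)
    }, integer(1))
  }
  data.frame(subject_id = subj,
             n_fixed = cnt("FIXED"),
             n_same = cnt("SAME"),
             n_diff = cnt("DIFF"),
             n_first = cnt("FIRST"))
}
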