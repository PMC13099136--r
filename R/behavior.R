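#' Percent correct over a set of trials
#'
#' `100 * correct / completed`; aborted trials are excluded.
#'
#' @param trials Trial table (rows of a session's `trials`).
#' @return Percentage in `[0, 100]`, or `NA` if no completed trials.
#' @export
percent_correct <- function(trials) {
  done <- trials[!trials$aborted, , drop = FALSE]
  if (!nrow(done)) return(NA_real_)
  100 * mean(done$correct)
}

#' Reaction time of a trial
#'
#' Interval from odor-port exit to fluid-well entry for go responses.
#' Trials without a well entry (correct no-go, and incorrect no-go on
#' rewarded trials, by extension of the same rule) are assigned the full
#' response window.
#'
#' @param trial One trial row (list or one-row data.frame).
#' @param response_window Response window (s), default 2.
#' @return Seconds, or `NA` if `poke_out` is missing.
#' @export
reaction_time <- function(trial, response_window = 2) {
  if (is.na(trial$poke_out %||% NA)) return(NA_real_)
  if (!is.na(trial$well_entry %||% NA)) trial$well_entry - trial$poke_out
  else response_window
}

#' Poke latency of a trial
#'
#' Time from house-light onset to odor-port entry.
#'
#' @param trial One trial row.
#' @return Seconds, or `NA` if the animal never poked.
#' @export
poke_latency <- function(trial) {
  if (is.na(trial$poke_in %||% NA)) return(NA_real_)
  trial$poke_in - trial$light_on
}

#' Behavioral summary table per session and trial type
#'
#' @param sessions List of `"session_record"`s (or one).
#' @return Data.frame, one row per (session, trial type): `percent_correct`,
#'   `reaction_time` (mean, s), `poke_latency` (mean, s), with sequence and
#'   position columns.
#' @export
behavior_table <- function(sessions) {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  rows <- list()
  for (ses in sessions) {
    tr <- ses$trials[!ses$trials$aborted, , drop = FALSE]
    rw <- ses$task$response_window
    tt <- trial_type_of(tr$sequence, tr$position)
    for (b in 1:8) {
      sub <- tr[tt == b, , drop = FALSE]
      if (!nrow(sub)) next
      rt <- vapply(seq_len(nrow(sub)), function(i)
        reaction_time(sub[i, ], rw), 0)
      pl <- vapply(seq_len(nrow(sub)), function(i)
        poke_latency(sub[i, ]), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        session = ses$session_id, trial_type = b,
        sequence = type_sequence(b), position = type_position(b),
        percent_correct = percent_correct(sub),
        reaction_time = mean(rt, na.rm = TRUE),
        poke_latency = mean(pl, na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}

#' Absolute S1-S2 difference scores per session and position
#'
#' For each of the three behavioral measures, the absolute difference
#' between the per-type session means of the two sequences at the same
#' position; invariant to swapping the sequence labels.
#'
#' @param table Output of [behavior_table()].
#' @return Data.frame, one row per (session, position, metric): `diff`.
#' @export
sequence_difference_scores <- function(table) {
  metrics <- c("percent_correct", "reaction_time", "poke_latency")
  rows <- list()
  for (s in unique(table$session)) {
    for (p in POSITIONS) {
      a <- table[table$session == s & table$position == p &
                   table$sequence == "S1", ]
      b <- table[table$session == s & table$position == p &
                   table$sequence == "S2", ]
      if (!nrow(a) || !nrow(b)) next
      for (m in metrics)
        rows[[length(rows) + 1L]] <- data.frame(
          session = s, position = p, metric = m,
          diff = abs(a[[m]] - b[[m]]))
    }
  }
  do.call(rbind, rows)
}
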