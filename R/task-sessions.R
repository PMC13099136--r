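#' Figure-8 odor sequence task configuration
#'
#' The figure-8 task presents two alternating four-position odor sequences
#' (S1, S2). The sequences carry unique odors at the outer positions P1 and
#' P4 and share identical odors at the middle positions P2 and P3, so the
#' middle positions are sensorially identical across sequences and define a
#' shared hidden state. Exactly P1 and P4 are rewarded (go trials), P2 and
#' P3 are not (no-go trials).
#'
#' Defaults encode the standard protocol: odor identities S1 = (5, 0, 1, 2)
#' and S2 = (3, 0, 1, 4); a 2 s response window at the fluid well; 4 s
#' inter-trial interval after correct trials and 8 s after errors; reward
#' delivered after a uniform random delay of 0.4--1.5 s; odor onset 0.5 s
#' after port entry; a 0.5 s minimum hold in the port; 5 s to initiate a
#' trial after light onset; and 40 repeats of each sequence (320 trials).
#'
#' @param odors_by_position_s1,odors_by_position_s2 Integer vectors of 4 odor
#'   identities for positions P1--P4 of each sequence.
#' @param reward_by_position Logical vector of 4; which positions are rewarded.
#' @param n_repeats_per_sequence Number of repeats of each sequence.
#' @param response_window Response window at the fluid well (s).
#' @param iti_correct,iti_error Inter-trial intervals (s).
#' @param reward_delay_range Length-2 numeric, uniform reward delay bounds (s).
#' @param odor_onset_delay Delay from port entry to odor onset (s).
#' @param min_hold Minimum time the animal must stay in the port (s).
#' @param light_timeout Time allowed to initiate a trial after light onset (s).
#' @return A validated object of class `"task_config"`.
#' @export
task_config <- function(odors_by_position_s1 = c(5L, 0L, 1L, 2L),
                        odors_by_position_s2 = c(3L, 0L, 1L, 4L),
                        reward_by_position = c(TRUE, FALSE, FALSE, TRUE),
                        n_repeats_per_sequence = 40L,
                        response_window = 2,
                        iti_correct = 4,
                        iti_error = 8,
                        reward_delay_range = c(0.4, 1.5),
                        odor_onset_delay = 0.5,
                        min_hold = 0.5,
                        light_timeout = 5) {
  cfg <- structure(list(
    odors_by_position_s1 = as.integer(odors_by_position_s1),
    odors_by_position_s2 = as.integer(odors_by_position_s2),
    reward_by_position = as.logical(reward_by_position),
    n_repeats_per_sequence = as.integer(n_repeats_per_sequence),
    response_window = response_window,
    iti_correct = iti_correct,
    iti_error = iti_error,
    reward_delay_range = as.numeric(reward_delay_range),
    odor_onset_delay = odor_onset_delay,
    min_hold = min_hold,
    light_timeout = light_timeout
  ), class = "task_config")
  validate_task_config(cfg)
  cfg
}

#' Validate a task configuration
#'
#' Checks the structural invariants of the figure-8 task: shared odors at
#' P2/P3, distinct odors at P1/P4, and reward exactly at P1 and P4.
#'
#' @param cfg A `"task_config"` object.
#' @return `cfg`, invisibly, if valid; otherwise a validation error.
#' @export
validate_task_config <- function(cfg) {
  s1 <- cfg$odors_by_position_s1; s2 <- cfg$odors_by_position_s2
  if (length(s1) != 4L || length(s2) != 4L)
    sg_validation_error("each sequence must list 4 odors")
  if (!all(s1[2:3] == s2[2:3]))
    sg_validation_error("positions P2 and P3 must share odor ids across sequences")
  if (s1[1] == s2[1] || s1[4] == s2[4])
    sg_validation_error("positions P1 and P4 must have distinct odor ids across sequences")
  if (!identical(cfg$reward_by_position, c(TRUE, FALSE, FALSE, TRUE)))
    sg_validation_error("exactly positions P1 and P4 must be rewarded")
  if (cfg$n_repeats_per_sequence < 1L)
    sg_validation_error("n_repeats_per_sequence must be >= 1")
  if (diff(cfg$reward_delay_range) < 0)
    sg_validation_error("reward_delay_range must be non-decreasing")
  invisible(cfg)
}

#' Trial type from (sequence, position)
#'
#' The 8 trial types are the combinations of sequence and position, numbered
#' in the fixed order S1-P1, S1-P2, S1-P3, S1-P4, S2-P1, ..., S2-P4 = 1..8.
#'
#' @param sequence Character vector of `"S1"`/`"S2"` (or a trial-record list
#'   with `sequence` and `position` fields, in which case `position` is
#'   ignored).
#' @param position Character vector of `"P1"`..`"P4"`.
#' @return Integer vector of trial types in 1..8.
#' @export
trial_type_of <- function(sequence, position = NULL) {
  if (is.list(sequence) && !is.null(sequence$sequence)) {
    position <- sequence$position
    sequence <- sequence$sequence
  }
  si <- match(as.character(sequence), SEQUENCES)
  pi <- match(as.character(position), POSITIONS)
  if (anyNA(si) || anyNA(pi))
    sg_validation_error("sequence must be S1/S2 and position P1..P4")
  (si - 1L) * 4L + pi
}

# sequence/position labels for a vector of trial types 1..8
type_sequence <- function(type) SEQUENCES[(type - 1L) %/% 4L + 1L]
type_position <- function(type) POSITIONS[(type - 1L) %% 4L + 1L]

#' Construct a session record
#'
#' A session bundles the task configuration, the trial table (one row per
#' trial, with behavioral event timestamps in seconds from session start),
#' the recorded units (spike-time vectors), and free-form metadata. Spike
#' times are rounded to microsecond resolution; duplicate spikes at the same
#' microsecond are collapsed with a warning.
#'
#' @param session_id Character id.
#' @param task A `"task_config"`.
#' @param trials A data.frame of trial records (see [empty_trial_table()] for
#'   the column set).
#' @param units List of units, each a list with `unit_id`, `group_label`, and
#'   numeric `spike_times`.
#' @param metadata Named list of free-form metadata.
#' @param validate Run [validate_session()]?
#' @return Object of class `"session_record"`.
#' @export
session_record <- function(session_id, task, trials, units = list(),
                           metadata = list(), validate = TRUE) {
  units <- lapply(units, function(u) {
    st <- round(as.numeric(u$spike_times), 6)
    if (anyDuplicated(st)) {
      warning("unit ", u$unit_id,
              ": duplicate spike timestamps collapsed at microsecond resolution")
      st <- unique(st)
    }
    list(unit_id = as.character(u$unit_id),
         group_label = as.character(u$group_label %||% "default"),
         spike_times = st)
  })
  trials <- as.data.frame(trials)
  for (col in intersect(TRIAL_EVENT_COLS, names(trials)))
    trials[[col]] <- round(as.numeric(trials[[col]]), 6)
  s <- structure(list(session_id = as.character(session_id), task = task,
                      trials = trials, units = units,
                      metadata = metadata),
                 class = "session_record")
  if (validate) validate_session(s)
  s
}

#' Column template for the trial table
#' @return Zero-row data.frame with the trial-record columns.
#' @export
empty_trial_table <- function() {
  data.frame(trial_index = integer(), sequence = character(),
             position = character(), odor_id = integer(),
             rewarded = logical(), response = character(),
             correct = logical(), aborted = logical(),
             light_on = numeric(), poke_in = numeric(), odor_on = numeric(),
             poke_out = numeric(), well_entry = numeric(),
             reward_time = numeric(), stringsAsFactors = FALSE)
}

#' Validate a session record
#'
#' Enforces the trial-record and spike-train invariants: present event
#' timestamps strictly increasing in task order; `reward_time` present iff
#' the trial was rewarded, responded go, and correct; `correct` consistent
#' with (rewarded, response); spike trains sorted, non-negative, duplicate
#' free. Aborted trials (port exit before the minimum hold) are exempt from
#' the response-outcome checks and are excluded from all analyses.
#'
#' @param s A `"session_record"`.
#' @return `s`, invisibly; a validation error names the offending trial/unit.
#' @export
validate_session <- function(s) {
  validate_task_config(s$task)
  tr <- s$trials
  need <- names(empty_trial_table())
  miss <- setdiff(need, names(tr))
  if (length(miss))
    sg_validation_error("trial table missing columns: ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    ts <- unlist(row[TRIAL_EVENT_COLS])
    ts <- ts[!is.na(ts)]
    if (length(ts) > 1L && any(diff(ts) <= 0))
      sg_validation_error("trial ", row$trial_index,
                          ": event timestamps not strictly increasing")
    if (isTRUE(row$aborted)) next
    go <- identical(row$response, "go")
    correct_expect <- (row$rewarded && go) || (!row$rewarded && !go)
    if (!identical(as.logical(row$correct), correct_expect))
      sg_validation_error("trial ", row$trial_index,
                          ": correct flag inconsistent with (rewarded, response)")
    has_rt <- !is.na(row$reward_time)
    if (has_rt != (row$rewarded && go && row$correct))
      sg_validation_error("trial ", row$trial_index,
                          ": reward_time must be present iff rewarded & go & correct")
  }
  for (u in s$units) {
    st <- u$spike_times
    if (length(st) && (is.unsorted(st, strictly = TRUE) || any(st < 0)))
      sg_validation_error("unit ", u$unit_id,
                          ": spike_times must be sorted, strictly increasing, non-negative")
  }
  n_expect <- 8L * s$task$n_repeats_per_sequence
  if (nrow(tr) > 0 && nrow(tr) == n_expect) {
    tt <- trial_type_of(tr$sequence, tr$position)
    if (!all(tabulate(tt, 8L) == s$task$n_repeats_per_sequence))
      sg_validation_error("complete session must have equal trial-type counts")
  }
  invisible(s)
}

#' Write a session container
#'
#' The container is a directory holding `session.json` (task configuration
#' and metadata), `trials.csv` (one row per trial, empty cell = absent
#' timestamp), and `spikes.csv` (`unit_id`, `group_label`, `spike_time`).
#' All times are seconds from session start, written at microsecond
#' precision; writes are byte-deterministic for identical input.
#'
#' @param session A validated `"session_record"`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) sg_stop("cannot create session directory ", path)

  manifest <- list(session_id = session$session_id,
                   task = unclass(session$task),
                   metadata = session$metadata)
  jsonlite::write_json(manifest, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  tr <- session$trials
  for (col in TRIAL_EVENT_COLS) tr[[col]] <- fmt_time(tr[[col]])
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE, na = "")

  sp <- do.call(rbind, lapply(session$units, function(u) {
    if (!length(u$spike_times))
      return(data.frame(unit_id = character(), group_label = character(),
                        spike_time = character()))
    data.frame(unit_id = u$unit_id, group_label = u$group_label,
               spike_time = fmt_time(u$spike_times))
  }))
  if (is.null(sp))
    sp <- data.frame(unit_id = character(), group_label = character(),
                     spike_time = character())
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

fmt_time <- function(x) {
  out <- ifelse(is.na(x), NA_character_, sprintf("%.6f", x))
  out
}

#' Read a session container
#'
#' Inverse of [write_session()]; all invariants are re-validated on load.
#'
#' @param path Directory written by [write_session()].
#' @return A `"session_record"`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "session.json")
  if (!file.exists(mf)) sg_stop("no session.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  task <- do.call(task_config, manifest$task[names(formals(task_config))])
  task$n_repeats_per_sequence <- as.integer(manifest$task$n_repeats_per_sequence)

  tr <- utils::read.csv(file.path(path, "trials.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(sequence = "character",
                                       position = "character",
                                       response = "character"))
  for (col in TRIAL_EVENT_COLS) tr[[col]] <- as.numeric(tr[[col]])
  tr$response[!is.na(tr$response) & tr$response == ""] <- NA
  tr$rewarded <- as.logical(tr$rewarded)
  tr$correct <- as.logical(tr$correct)
  tr$aborted <- as.logical(tr$aborted)

  sp <- utils::read.csv(file.path(path, "spikes.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(unit_id = "character",
                                       group_label = "character",
                                       spike_time = "numeric"))
  ids <- unique(sp$unit_id)
  units <- lapply(ids, function(id) {
    rows <- sp[sp$unit_id == id, ]
    list(unit_id = id, group_label = rows$group_label[1],
         spike_times = rows$spike_time)
  })
  metadata <- as.list(manifest$metadata %||% list())
  session_record(manifest$session_id, task, tr, units, metadata)
}

#' @export
print.session_record <- function(x, ...) {
  cat("<session_record> ", x$session_id, "\n", sep = "")
  cat("  trials: ", nrow(x$trials), " (", sum(!x$trials$aborted & x$trials$correct),
      " correct)\n", sep = "")
  cat("  units:  ", length(x$units), "\n", sep = "")
  invisible(x)
}
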