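#' Behavioral profile for the session simulator
#'
#' Per-trial-type accuracy probabilities and lognormal latency parameters.
#' Sequence-dependent shifts are additive on the log scale and applied to S2
#' trials at the given positions; a compressed (well-generalized) population
#' has all shifts at zero.
#'
#' @param accuracy Length-8 probability of a correct response per trial type
#'   (types 1..8 = S1-P1..S2-P4).
#' @param poke_meanlog,poke_sdlog Lognormal parameters of the latency from
#'   light onset to odor-port entry (s).
#' @param rt_meanlog,rt_sdlog Lognormal parameters of the reaction time from
#'   port exit to well entry on go responses (s); draws are capped just
#'   under the response window.
#' @param unpoke_meanlog,unpoke_sdlog Lognormal parameters of the extra hold
#'   time after the 0.5 s minimum before port exit (s).
#' @param seq_shift_poke,seq_shift_rt Length-4 additive log-scale shifts for
#'   S2 trials at P1..P4.
#' @param abort_prob Probability a trial is aborted by early port exit.
#' @return Object of class `"behavior_profile"`.
#' @export
behavior_profile <- function(accuracy = rep(0.95, 8),
                             poke_meanlog = log(0.5), poke_sdlog = 0.35,
                             rt_meanlog = log(0.7), rt_sdlog = 0.3,
                             unpoke_meanlog = log(0.15), unpoke_sdlog = 0.4,
                             seq_shift_poke = rep(0, 4),
                             seq_shift_rt = rep(0, 4),
                             abort_prob = 0) {
  structure(list(accuracy = rep_len(accuracy, 8), poke_meanlog = poke_meanlog,
                 poke_sdlog = poke_sdlog, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog, unpoke_meanlog = unpoke_meanlog,
                 unpoke_sdlog = unpoke_sdlog,
                 seq_shift_poke = rep_len(seq_shift_poke, 4),
                 seq_shift_rt = rep_len(seq_shift_rt, 4),
                 abort_prob = abort_prob),
            class = "behavior_profile")
}

# A population-level response component: a temporal profile over the 9
# epochs, a trial-type weighting, and a slow drift over the session.
# Components whose type weight is constant across all 8 trial types are
# "position-general" -- they express the same pattern on every trial and are
# the planted analogue of the global session dynamics seen in well-trained
# controls.
population_component <- function(name, temporal, weight = c("const",
                                 "rewarded", "nonrewarded", "position"),
                                 positions = NULL,
                                 drift = c("const", "ramp", "halfsine"),
                                 amplitude = 0.6) {
  weight <- match.arg(weight)
  drift <- match.arg(drift)
  stopifnot(length(temporal) == 9L, all(temporal >= 0))
  list(name = name, temporal = as.numeric(temporal), weight = weight,
       positions = positions, drift = drift, amplitude = amplitude,
       position_general = (weight == "const"))
}

component_type_weight <- function(comp, position, rewarded) {
  switch(comp$weight,
         const = rep(1, length(position)),
         rewarded = as.numeric(rewarded),
         nonrewarded = as.numeric(!rewarded),
         position = as.numeric(position %in% comp$positions))
}

component_drift <- function(comp, k, K) {
  u <- if (K > 1L) (k - 1) / (K - 1) else rep(0, length(k))
  switch(comp$drift, const = rep(1, length(k)), ramp = u,
         halfsine = sin(pi * u))
}

# Template-level population components. Both templates share reward-outcome
# coding and a whole-trial anticipatory modulation on rewarded trials (both
# ubiquitous in OFC; no purely trial-type-independent activity exists unless
# planted); the compressed template adds three position-general components,
# two with slow drift over the session.
reward_coding_components <- function() list(
  population_component("reward_pos", c(0, 0, 0, 0, .3, 1, 1, .6, 0),
                       weight = "rewarded", amplitude = 0.9),
  population_component("reward_neg", c(0, 0, 0, 0, 0, .4, 1, .8, .4),
                       weight = "nonrewarded", amplitude = 0.7),
  population_component("reward_anticipation",
                       c(.8, .9, 1, 1, .9, .7, .5, .4, .3),
                       weight = "rewarded", amplitude = 1.2))

# Position-coding components shared by both templates: odor-sampling
# responses specific to each position (sequence-independent -- at P2/P3
# the odors are identical across sequences, and at P1/P4 the response is
# to the position's odor pair). Their per-trial amplitude jitter carries
# the population's information-limiting correlated noise.
position_components <- function() lapply(POSITIONS, function(p)
  population_component(paste0(tolower(p), "_odor"),
                       c(0, 0, .4, 1, .6, 0, 0, 0, 0),
                       weight = "position", positions = p, amplitude = 0.6))

compressed_components <- function() c(
  reward_coding_components(),
  position_components(),
  list(
  population_component("early_broad", c(1, 1, .6, .2, 0, 0, 0, 0, 0),
                       weight = "const", drift = "const", amplitude = 1.5),
  population_component("session_ramp", c(0, 0, .3, .7, 1, .7, .3, 0, 0),
                       weight = "const", drift = "ramp", amplitude = 1.5),
  population_component("session_wave", c(0, 0, 0, 0, 0, 0, .3, .8, 1),
                       weight = "const", drift = "halfsine", amplitude = 1.5)))

differentiated_components <- function() c(
  reward_coding_components(),
  position_components())

# Epochs-by-positions mask of where sequence asymmetry is planted.
seq_selectivity_mask <- function(name) {
  m <- matrix(FALSE, 9, 4, dimnames = list(EPOCHS, POSITIONS))
  if (name == "compressed") {
    m["Odor", c("P1", "P4")] <- TRUE      # physically different odors only
  } else {
    m[4:6, "P1"] <- TRUE                  # Odor, Unpoke, Choice
    m[7:9, "P3"] <- TRUE                  # end of P3: Outcome, postOut, ITI-b
    m[2:9, "P4"] <- TRUE                  # most epochs of P4
  }
  m
}

#' Population template with planted ground truth
#'
#' Defines the distribution of unit tuning profiles and the behavioral
#' profile for a simulated group. The `"compressed"` template generalizes
#' over sequences: sequence asymmetry exists only during the Odor epoch at
#' P1/P4 (where the odors physically differ), behavior is sequence
#' symmetric, and the population carries three position-general components
#' (one broadly active early component and two with slow drift across the
#' session). The `"differentiated"` template plants sequence-selective
#' gain in a fraction of units at P1, the late epochs of P3, and most
#' epochs of P4, shifts behavior between sequences, and has no
#' position-general components.
#'
#' @param name `"compressed"` or `"differentiated"`.
#' @param n_units Units per simulated session.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline-rate parameters
#'   (median 5 Hz by default).
#' @param tuning_sdlog Lognormal SD of the per-unit epoch-by-position gains.
#' @param selective_fraction Fraction of units carrying sequence-selective
#'   gain at the template's designated (epoch, position) cells.
#' @param seq_gain_meanlog,seq_gain_sdlog Lognormal parameters of the
#'   planted sequence gain (> 1) for selective units.
#' @param component_load_shape,component_load_rate Gamma parameters of the
#'   per-unit loadings on the population components.
#' @param trial_noise_sdlog Lognormal SD of the shared per-trial population
#'   gain (correlated trial-to-trial excitability noise; 0 disables it).
#' @param component_noise_sdlog Lognormal SD of each population component's
#'   per-trial amplitude jitter, shared across units (differential,
#'   information-limiting noise along the component directions).
#' @param behavior A [behavior_profile()]; defaults depend on `name`.
#' @return Object of class `"population_template"`.
#' @export
population_template <- function(name = c("compressed", "differentiated"),
                                n_units = 300,
                                baseline_meanlog = log(5),
                                baseline_sdlog = 0.6,
                                tuning_sdlog = 0.3,
                                selective_fraction = 0.3,
                                seq_gain_meanlog = log(2),
                                seq_gain_sdlog = 0.25,
                                component_load_shape = 2,
                                component_load_rate = 4,
                                trial_noise_sdlog = 0.2,
                                component_noise_sdlog = 0.25,
                                behavior = NULL) {
  name <- match.arg(name)
  if (is.null(behavior)) {
    behavior <- if (name == "compressed") behavior_profile()
    else behavior_profile(
      accuracy = c(0.95, 0.92, 0.95, 0.95, 0.89, 0.92, 0.89, 0.89),
      seq_shift_poke = c(0.2, 0, 0.2, 0.2),
      seq_shift_rt = c(0.15, 0, 0.15, 0.15))
  }
  structure(list(name = name, n_units = as.integer(n_units),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 tuning_sdlog = tuning_sdlog,
                 selective_fraction = selective_fraction,
                 seq_gain_meanlog = seq_gain_meanlog,
                 seq_gain_sdlog = seq_gain_sdlog,
                 component_load_shape = component_load_shape,
                 component_load_rate = component_load_rate,
                 trial_noise_sdlog = trial_noise_sdlog,
                 component_noise_sdlog = component_noise_sdlog,
                 components = if (name == "compressed")
                   compressed_components() else differentiated_components(),
                 seq_mask = seq_selectivity_mask(name),
                 behavior = behavior),
            class = "population_template")
}

#' Generate the trial schedule for a session
#'
#' Alternating S1/S2 blocks of positions P1..P4, `n_repeats_per_sequence`
#' repeats of each sequence; the starting sequence is drawn pseudorandomly
#' from the seeded RNG.
#'
#' @param task A [task_config()].
#' @param seed Integer seed.
#' @return Data.frame with `sequence`, `position`, `odor_id`, `rewarded`
#'   (one row per trial) and the task attached as attribute `"task"`.
#' @export
make_task_schedule <- function(task = task_config(), seed = 1) {
  start <- with_seed(derive_seed(seed, "schedule_start"),
                     sample(SEQUENCES, 1))
  seqs <- rep(if (start == "S1") SEQUENCES else rev(SEQUENCES),
              task$n_repeats_per_sequence)
  sched <- do.call(rbind, lapply(seqs, function(sq) data.frame(
    sequence = sq, position = POSITIONS,
    odor_id = if (sq == "S1") task$odors_by_position_s1
              else task$odors_by_position_s2,
    rewarded = task$reward_by_position)))
  rownames(sched) <- NULL
  attr(sched, "task") <- task
  sched
}

#' Simulate behavioral event timestamps for a schedule
#'
#' Draws correctness per trial from the profile's per-type accuracy, then
#' lays out event timestamps obeying the task timing rules: odor onset 0.5 s
#' after port entry, a 0.5 s minimum hold, a 2 s response window, reward
#' after a uniform 0.4--1.5 s delay on rewarded go trials, and 4 s / 8 s
#' inter-trial intervals after correct / error trials. Correct no-go trials
#' have no well entry.
#'
#' @param schedule Output of [make_task_schedule()].
#' @param profile A [behavior_profile()].
#' @param seed Integer seed.
#' @param task A [task_config()]; defaults to the schedule's attribute.
#' @return A trial table data.frame (see [empty_trial_table()]).
#' @export
simulate_behavior <- function(schedule, profile = behavior_profile(),
                              seed = 1, task = attr(schedule, "task")) {
  if (is.null(task)) task <- task_config()
  n <- nrow(schedule)
  tt <- trial_type_of(schedule$sequence, schedule$position)
  pidx <- match(schedule$position, POSITIONS)
  s2 <- schedule$sequence == "S2"
  with_seed(derive_seed(seed, "behavior"), {
    correct <- stats::runif(n) < profile$accuracy[tt]
    aborted <- stats::runif(n) < profile$abort_prob
    poke_lat <- pmin(stats::rlnorm(n, profile$poke_meanlog +
                                     ifelse(s2, profile$seq_shift_poke[pidx], 0),
                                   profile$poke_sdlog),
                     task$light_timeout - 0.2)
    unpoke_lat <- stats::rlnorm(n, profile$unpoke_meanlog, profile$unpoke_sdlog)
    rt <- pmin(stats::rlnorm(n, profile$rt_meanlog +
                               ifelse(s2, profile$seq_shift_rt[pidx], 0),
                             profile$rt_sdlog),
               task$response_window - 0.05)
    rdelay <- stats::runif(n, task$reward_delay_range[1],
                           task$reward_delay_range[2])
    abort_hold <- stats::runif(n, 0.05, task$min_hold - 0.05)
  })
  # all within-trial intervals are independent draws, so the whole layout
  # vectorizes; only the trial start times need a cumulative sum
  rewarded <- schedule$rewarded
  go <- ifelse(correct, rewarded, !rewarded)
  go[aborted] <- NA
  correct[aborted] <- NA
  d_poke_in <- poke_lat
  d_odor_on <- d_poke_in + task$odor_onset_delay
  d_poke_out <- ifelse(aborted, d_odor_on + abort_hold,
                       d_odor_on + task$min_hold + unpoke_lat)
  d_well <- ifelse(!aborted & go %in% TRUE, d_poke_out + rt, NA_real_)
  d_reward <- ifelse(!aborted & rewarded & go %in% TRUE, d_well + rdelay,
                     NA_real_)
  d_end <- ifelse(aborted, d_poke_out,
                  pmax(d_poke_out + task$response_window, d_reward,
                       na.rm = TRUE))
  iti <- ifelse(!aborted & correct %in% TRUE, task$iti_correct,
                task$iti_error)
  light_on <- 1.0 + c(0, cumsum((d_end + iti)[-n]))
  out <- data.frame(trial_index = seq_len(n), sequence = schedule$sequence,
                    position = schedule$position,
                    odor_id = schedule$odor_id, rewarded = rewarded,
                    response = ifelse(is.na(go), NA_character_,
                                      ifelse(go, "go", "no-go")),
                    correct = correct, aborted = aborted,
                    light_on = light_on, poke_in = light_on + d_poke_in,
                    odor_on = light_on + d_odor_on,
                    poke_out = light_on + d_poke_out,
                    well_entry = light_on + d_well,
                    reward_time = light_on + d_reward,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tuning profile of one simulated unit
#'
#' A unit's expected rate is
#' `baseline * (1 + sum_e (G[e, p] * s - 1) * bump_e(t)) * (1 + global(t, k))`
#' where `G` is the epoch-by-position gain matrix, `s` the sequence gain
#' (applied where the profile's mask and the trial's sequence match), the
#' bumps are raised cosines tied to the nine epoch anchors, and `global`
#' sums the population components weighted by the unit's loadings. Rates are
#' floored at zero; spikes are drawn by thinning an inhomogeneous Poisson
#' process with piecewise-constant rate over 10 ms sub-bins.
#'
#' @param baseline_rate Baseline rate (Hz).
#' @param epoch_gains 9 x 4 (epochs x positions) multiplicative gain matrix.
#' @param seq_gain Length-4 sequence gain per position (1 = symmetric).
#' @param seq_dir +1 to boost S1, -1 to boost S2, where the mask applies.
#' @param seq_mask 9 x 4 logical; where the sequence gain applies.
#' @param components List of population components (see
#'   [population_template()]).
#' @param loadings Numeric, one non-negative loading per component.
#' @return Object of class `"unit_tuning_profile"`.
#' @export
unit_tuning_profile <- function(baseline_rate = 5,
                                epoch_gains = matrix(1, 9, 4),
                                seq_gain = rep(1, 4), seq_dir = 1L,
                                seq_mask = matrix(FALSE, 9, 4),
                                components = list(), loadings = numeric(0)) {
  structure(list(baseline_rate = baseline_rate, epoch_gains = epoch_gains,
                 seq_gain = rep_len(seq_gain, 4), seq_dir = seq_dir,
                 seq_mask = seq_mask, components = components,
                 loadings = loadings),
            class = "unit_tuning_profile")
}

# Raised-cosine epoch response bump. Centered 0.35 s after the anchor (the
# middle of the 0.1-0.6 s post-event analysis window; neural responses lag
# their triggering events), half-width 0.3 s.
BUMP_CENTER <- 0.35
BUMP_HALFWIDTH <- 0.3

bump_activation <- function(t, anchor) {
  u <- (t - anchor - BUMP_CENTER) / BUMP_HALFWIDTH
  ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
}

# Precompute the simulation grid for a trial table: 10 ms sub-bin start
# times covering each trial's modulation window, the per-point trial index,
# and the 9 epoch bump activations. Unit independent, so shared across a
# session's units.
build_sim_grid <- function(trials, response_window = 2, dt = 0.01) {
  anchors <- anchor_matrix(trials, response_window)
  ok <- stats::complete.cases(anchors)
  win_lo <- anchors[, 1]
  win_hi <- anchors[, 9] + BUMP_CENTER + BUMP_HALFWIDTH
  pieces <- lapply(which(ok), function(i)
    seq(win_lo[i], win_hi[i] - dt / 2, by = dt))
  t_all <- unlist(pieces)
  trial_of <- rep(which(ok), lengths(pieces))
  act <- matrix(0, length(t_all), 9L)
  for (e in 1:9) act[, e] <- bump_activation(t_all, anchors[trial_of, e])
  K <- nrow(trials)
  list(t = t_all, trial_of = trial_of, act = act, dt = dt,
       anchors = anchors, ok = ok,
       win_lo = win_lo, win_hi = win_hi, K = K,
       pos_idx = match(trials$position, POSITIONS),
       s1 = trials$sequence == "S1",
       rewarded = trials$rewarded,
       session_end = max(win_hi[ok], 0) + 1)
}

# Per-session cache of the component activations on the grid (identical for
# all units sharing a template's component list).
grid_component_cache <- function(grid, components) {
  if (!length(components))
    return(list(temp_act = NULL, twdw = NULL))
  temp_act <- grid$act %*%
    vapply(components, `[[`, numeric(9), "temporal")       # points x C
  twdw <- vapply(components, function(comp)
    component_type_weight(comp, POSITIONS[grid$pos_idx], grid$rewarded) *
      component_drift(comp, seq_len(grid$K), grid$K),
    numeric(grid$K))                                       # trials x C
  twdw <- matrix(twdw, grid$K)
  if (!is.null(grid$comp_jitter)) twdw <- twdw * grid$comp_jitter
  list(temp_act = temp_act, twdw = twdw)
}

# Expected rate (Hz) at every grid point for one unit.
unit_rate_on_grid <- function(profile, grid, cache = NULL) {
  # sequence-gain factor per (epoch, position) and sequence: masked cells
  # are boosted on the sequence their direction points to; the direction
  # may be a scalar (one preferred sequence) or a 9 x 4 matrix (cellwise
  # remapping-like divergence)
  dir <- profile$seq_dir
  if (length(dir) == 1L) dir <- matrix(dir, 9, 4)
  gmat <- matrix(rep(profile$seq_gain, each = 9), 9, 4)
  F1 <- ifelse(profile$seq_mask & dir > 0, gmat, 1)        # S1 factor
  F2 <- ifelse(profile$seq_mask & dir < 0, gmat, 1)        # S2 factor
  G1 <- t(profile$epoch_gains * F1)                        # 4 x 9
  G2 <- t(profile$epoch_gains * F2)
  p <- grid$pos_idx
  Gtot <- G1[p, , drop = FALSE]
  Gtot[!grid$s1, ] <- G2[p[!grid$s1], , drop = FALSE]      # K x 9
  gain <- 1 + rowSums(grid$act * (Gtot - 1)[grid$trial_of, , drop = FALSE])
  glob <- 0
  if (length(profile$components)) {
    if (is.null(cache)) cache <- grid_component_cache(grid, profile$components)
    amp <- profile$loadings *
      vapply(profile$components, `[[`, 0, "amplitude")
    glob <- (cache$temp_act *
               cache$twdw[grid$trial_of, , drop = FALSE]) %*% amp
  }
  tg <- if (is.null(grid$trial_gain)) 1 else grid$trial_gain[grid$trial_of]
  pmax(0, profile$baseline_rate * tg * pmax(0, gain) * (1 + as.numeric(glob)))
}

#' Simulate a spike train for one unit
#'
#' Draws inhomogeneous-Poisson spikes with the profile's rate function:
#' piecewise-constant over 10 ms sub-bins inside each trial's modulation
#' window, constant baseline elsewhere in the session.
#'
#' @param profile A [unit_tuning_profile()].
#' @param trials Trial table with behavioral timestamps.
#' @param seed Integer seed.
#' @param unit_id,group_label Identifiers for the resulting unit.
#' @param grid Optional precomputed grid (shared across a session's units).
#' @param cache Optional component-activation cache from the same grid.
#' @return A unit list (`unit_id`, `group_label`, sorted `spike_times`).
#' @export
simulate_unit <- function(profile, trials, seed = 1, unit_id = "u1",
                          group_label = "default", grid = NULL,
                          cache = NULL) {
  if (is.null(grid)) grid <- build_sim_grid(trials)
  rate <- unit_rate_on_grid(profile, grid, cache)
  with_seed(derive_seed(seed, "unit", unit_id), {
    counts <- stats::rpois(length(rate), rate * grid$dt)
    idx <- rep(seq_along(counts), counts)
    spikes_in <- grid$t[idx] + stats::runif(length(idx), 0, grid$dt)
    # homogeneous baseline in the gaps between trial windows
    gaps_lo <- c(0, grid$win_hi[grid$ok])
    gaps_hi <- c(grid$win_lo[grid$ok], grid$session_end)
    glen <- pmax(0, gaps_hi - gaps_lo)
    ng <- stats::rpois(length(glen), profile$baseline_rate * glen)
    spikes_out <- unlist(Map(function(lo, len, n)
      if (n > 0) lo + stats::runif(n, 0, len) else numeric(0),
      gaps_lo, glen, ng))
    st <- sort(c(spikes_in, spikes_out))
  })
  st <- unique(round(st, 6))
  list(unit_id = unit_id, group_label = group_label, spike_times = st)
}

# Draw one unit's tuning profile from a template.
sample_unit_profile <- function(template, seed) {
  with_seed(seed, {
    baseline <- stats::rlnorm(1, template$baseline_meanlog,
                              template$baseline_sdlog)
    epoch_gains <- matrix(stats::rlnorm(36, 0, template$tuning_sdlog), 9, 4)
    selective <- stats::runif(1) < template$selective_fraction
    seq_gain <- if (selective)
      rep(stats::rlnorm(1, template$seq_gain_meanlog,
                        template$seq_gain_sdlog), 4) else rep(1, 4)
    seq_gain <- pmax(seq_gain, 1)
    # independent boost direction per masked cell: the asymmetry remaps
    # the selective unit across sequences rather than scaling it uniformly
    seq_dir <- matrix(sign(stats::runif(36) - 0.5), 9, 4)
    loadings <- stats::rgamma(length(template$components),
                              template$component_load_shape,
                              template$component_load_rate)
  })
  list(profile = unit_tuning_profile(
         baseline_rate = baseline, epoch_gains = epoch_gains,
         seq_gain = seq_gain, seq_dir = seq_dir,
         seq_mask = template$seq_mask, components = template$components,
         loadings = loadings),
       selective = selective, seq_gain = seq_gain[1],
       baseline = baseline, loadings = loadings)
}

#' Simulate one complete session from a template
#'
#' @param template A [population_template()].
#' @param seed Integer seed.
#' @param session_id Session identifier.
#' @param task A [task_config()].
#' @return List: `session` (a `"session_record"`) and `truth` (per-unit
#'   planted parameters).
#' @export
simulate_session <- function(template, seed = 1, session_id = "sim1",
                             task = task_config()) {
  sched <- make_task_schedule(task, derive_seed(seed, "sched", session_id))
  trials <- simulate_behavior(sched, template$behavior,
                              derive_seed(seed, "beh", session_id), task)
  grid <- build_sim_grid(trials, task$response_window)
  grid$trial_gain <- with_seed(derive_seed(seed, "trialgain", session_id),
                               stats::rlnorm(nrow(trials), 0,
                                             template$trial_noise_sdlog))
  grid$comp_jitter <- with_seed(
    derive_seed(seed, "compjitter", session_id),
    matrix(stats::rlnorm(nrow(trials) * length(template$components), 0,
                         template$component_noise_sdlog),
           nrow(trials)))
  cache <- grid_component_cache(grid, template$components)
  units <- vector("list", template$n_units)
  truth <- vector("list", template$n_units)
  for (u in seq_len(template$n_units)) {
    uid <- sprintf("%s_u%03d", session_id, u)
    draw <- sample_unit_profile(template,
                                derive_seed(seed, "profile", session_id, u))
    units[[u]] <- simulate_unit(draw$profile, trials,
                                derive_seed(seed, "spikes", session_id),
                                unit_id = uid, group_label = template$name,
                                grid = grid, cache = cache)
    truth[[u]] <- data.frame(session = session_id, unit_id = uid,
                             baseline = draw$baseline,
                             seq_selective = draw$selective,
                             seq_gain = draw$seq_gain)
    truth[[u]] <- cbind(truth[[u]],
                        stats::setNames(as.data.frame(t(draw$loadings)),
                                        paste0("load_",
                                               vapply(template$components,
                                                      `[[`, "", "name"))))
  }
  session <- session_record(session_id, task, trials, units,
                            metadata = list(template = template$name,
                                            seed = seed))
  list(session = session, truth = do.call(rbind, truth),
       trial_gain = grid$trial_gain)
}

#' Simulate a group of sessions with ground truth
#'
#' @param template A [population_template()].
#' @param n_sessions Number of independent sessions.
#' @param seed Integer master seed.
#' @param task A [task_config()].
#' @return List of class `"simulated_group"`: `sessions` (list of
#'   `"session_record"`), `ground_truth` (template name, per-unit table,
#'   selectivity mask, component definitions, behavior profile, seed).
#' @export
simulate_group <- function(template, n_sessions = 1, seed = 1,
                           task = task_config()) {
  sims <- lapply(seq_len(n_sessions), function(s)
    simulate_session(template, derive_seed(seed, "session", s),
                     session_id = sprintf("%s%02d", template$name, s),
                     task = task))
  structure(list(
    sessions = lapply(sims, `[[`, "session"),
    ground_truth = list(template = template$name,
                        units = do.call(rbind, lapply(sims, `[[`, "truth")),
                        seq_mask = template$seq_mask,
                        components = template$components,
                        behavior = template$behavior,
                        seed = seed)),
    class = "simulated_group")
}
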