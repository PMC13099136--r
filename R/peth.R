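#' Epoch anchors for one trial
#'
#' Each analyzable trial is divided into nine epochs anchored on task events:
#' `ITI-a` (0.7 s before house-light onset), `Light`, `Poke`, `Odor`,
#' `Unpoke`, `Choice`, `Outcome`, `postOut`, and `ITI-b`. On rewarded correct
#' go trials `Choice` is the well-entry moment and `Outcome` the reward
#' delivery; otherwise `Choice` is the end of the 2 s response window
#' (port exit + 2 s) and `Outcome` follows 0.7 s later. `postOut` and
#' `ITI-b` follow at successive 0.7 s steps.
#'
#' @param trial One row of a session trial table (data.frame or list).
#' @param response_window Response window (s), default 2.
#' @return Named numeric vector of 9 anchor times (s), or `NULL` if a
#'   required timestamp (`light_on`, `poke_in`, `odor_on`, `poke_out`) is
#'   missing, which flags the trial unanalyzable.
#' @export
anchor_epochs <- function(trial, response_window = 2) {
  need <- c(trial$light_on, trial$poke_in, trial$odor_on, trial$poke_out)
  if (length(need) < 4L || anyNA(need)) return(NULL)
  choice <- if (!is.na(trial$reward_time %||% NA)) trial$well_entry
            else trial$poke_out + response_window
  outcome <- if (!is.na(trial$reward_time %||% NA)) trial$reward_time
             else choice + 0.7
  a <- c(trial$light_on - 0.7, trial$light_on, trial$poke_in, trial$odor_on,
         trial$poke_out, choice, outcome, outcome + 0.7, outcome + 1.4)
  names(a) <- EPOCHS
  a
}

# Anchor matrix (n_trials x 9) for a trial table; NA rows = unanalyzable.
anchor_matrix <- function(trials, response_window = 2) {
  out <- matrix(NA_real_, nrow(trials), 9L, dimnames = list(NULL, EPOCHS))
  for (i in seq_len(nrow(trials))) {
    a <- anchor_epochs(trials[i, ], response_window)
    if (!is.null(a)) out[i, ] <- a
  }
  out
}

#' Spike binning parameters
#'
#' The peri-event window spans 200 ms before to 600 ms after each epoch
#' anchor, divided into eight 100 ms bins; trial-wise smoothing uses a
#' Gaussian kernel with a 50 ms standard deviation.
#'
#' @param pre_event,post_event Window extent around the anchor (s).
#' @param bin_width Bin width (s).
#' @param smooth_sigma Gaussian kernel SD (s).
#' @return Object of class `"binning_params"`.
#' @export
binning_params <- function(pre_event = 0.2, post_event = 0.6,
                           bin_width = 0.1, smooth_sigma = 0.05) {
  n_bins <- (pre_event + post_event) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    sg_validation_error("(pre_event + post_event) must be a multiple of bin_width")
  structure(list(pre_event = pre_event, post_event = post_event,
                 bin_width = bin_width, smooth_sigma = smooth_sigma,
                 n_bins = as.integer(round(n_bins))),
            class = "binning_params")
}

#' Bin spikes around an anchor
#'
#' Bin `i` (1-based) covers the half-open interval
#' `[anchor - pre + width * (i - 1), anchor - pre + width * i)`; a spike at
#' the anchor itself therefore falls in the first post-anchor bin, and a
#' spike at exactly `anchor + post_event` is excluded.
#'
#' @param spikes Sorted numeric spike times (s).
#' @param anchor Anchor time (s).
#' @param params A [binning_params()] object.
#' @return Integer vector of counts, one per bin.
#' @export
bin_spikes <- function(spikes, anchor, params = binning_params()) {
  # edges rounded to nanoseconds so decimal boundaries are exact
  edges <- round(anchor - params$pre_event +
                   params$bin_width * (0:params$n_bins), 9)
  idx <- findInterval(spikes, edges)
  tabulate(idx[idx >= 1L & idx <= params$n_bins], params$n_bins)
}

# Discrete Gaussian kernel over integer bin offsets, truncated at +-3 sigma
# (in bins) and renormalized to unit sum; sigma -> 0 gives the identity.
gaussian_kernel <- function(params) {
  sb <- params$smooth_sigma / params$bin_width
  if (sb < 1e-8) return(c(`0` = 1))
  radius <- floor(3 * sb + 1e-9)
  k <- -radius:radius
  w <- exp(-k^2 / (2 * sb^2))
  stats::setNames(w / sum(w), k)
}

# Banded n x n convolution matrix for the kernel (zero padding at edges).
kernel_matrix <- function(params, n = params$n_bins) {
  w <- gaussian_kernel(params)
  off <- as.integer(names(w))
  K <- matrix(0, n, n)
  for (j in seq_along(off)) {
    i <- seq_len(n)
    tgt <- i + off[j]
    ok <- tgt >= 1 & tgt <= n
    K[cbind(i[ok], tgt[ok])] <- K[cbind(i[ok], tgt[ok])] + w[j]
  }
  K
}

#' Smooth binned counts into a rate vector
#'
#' Convolves per-trial bin counts with a discrete Gaussian kernel (SD in
#' seconds, `smooth_sigma / bin_width` bins, truncated at three SDs and
#' renormalized to unit sum) and converts to firing rate in Hz. Mass is
#' conserved except for truncation at the window edges.
#'
#' @param counts Numeric vector of bin counts from [bin_spikes()].
#' @param params A [binning_params()] object.
#' @return Numeric rate vector (Hz), same length as `counts`.
#' @export
smooth_counts <- function(counts, params = binning_params()) {
  as.numeric(counts %*% kernel_matrix(params, length(counts))) /
    params$bin_width
}

#' Mean epoch firing rate from the post-event window
#'
#' Averages the smoothed rate over the bins covering 100--600 ms after the
#' anchor (bins 4..8 of the standard 8-bin window), the single per-epoch
#' activity measure used by all selectivity and decoding analyses.
#'
#' @param rates Smoothed 8-bin rate vector (Hz).
#' @param params A [binning_params()] object.
#' @return Scalar mean rate (Hz).
#' @export
epoch_mean_rate <- function(rates, params = binning_params()) {
  first_post <- as.integer(round(params$pre_event / params$bin_width)) + 2L
  mean(rates[first_post:params$n_bins])
}

#' Per-session epoch rate array
#'
#' Computes, for every unit and analyzable trial, the smoothed per-bin rates
#' around all nine epoch anchors, and their post-event means.
#'
#' @param session A `"session_record"`.
#' @param params A [binning_params()] object.
#' @return List with `mean_rates` (units x trials x 9 epochs array of
#'   post-event mean rates, Hz; `NA` for unanalyzable trials), `bin_rates`
#'   (units x trials x 72 array of smoothed per-bin rates, epoch-major), and
#'   `analyzable` (logical per trial).
#' @export
epoch_rates <- function(session, params = binning_params()) {
  tr <- session$trials
  anchors <- anchor_matrix(tr, session$task$response_window)
  analyzable <- stats::complete.cases(anchors) & !tr$aborted
  n_tr <- nrow(tr); n_u <- length(session$units); nb <- params$n_bins
  K <- kernel_matrix(params)
  mean_rates <- array(NA_real_, c(n_u, n_tr, 9L),
                      dimnames = list(NULL, NULL, EPOCHS))
  bin_rates <- array(NA_real_, c(n_u, n_tr, 9L * nb))
  idx_tr <- which(analyzable)
  if (!length(idx_tr)) return(list(mean_rates = mean_rates,
                                   bin_rates = bin_rates,
                                   analyzable = analyzable))
  # Edge grid: for each analyzable trial and epoch, nb + 1 edges.
  offs <- round(-params$pre_event + params$bin_width * (0:nb), 9)
  anc <- anchors[idx_tr, , drop = FALSE]                 # m x 9
  m <- length(idx_tr)
  edges <- array(0, c(m, 9L, nb + 1L))
  for (e in 1:9) edges[, e, ] <- outer(anc[, e], offs, `+`)
  first_post <- as.integer(round(params$pre_event / params$bin_width)) + 2L
  for (u in seq_len(n_u)) {
    f <- findInterval(as.vector(edges), session$units[[u]]$spike_times)
    f <- array(f, c(m, 9L, nb + 1L))
    counts <- f[, , -1L, drop = FALSE] - f[, , -(nb + 1L), drop = FALSE]
    for (e in 1:9) {
      sm <- (matrix(counts[, e, ], m, nb) %*% K) / params$bin_width # m x nb Hz
      bin_rates[u, idx_tr, (e - 1L) * nb + seq_len(nb)] <- sm
      mean_rates[u, idx_tr, e] <- rowMeans(sm[, first_post:nb, drop = FALSE])
    }
  }
  list(mean_rates = mean_rates, bin_rates = bin_rates, analyzable = analyzable)
}

# Select n_per_type correct, analyzable trials per trial type; seeded per
# (session, type) so selection is independent of session order.
select_trials <- function(session, analyzable, n_per_type, seed) {
  tr <- session$trials
  usable <- which(analyzable & tr$correct %in% TRUE)
  tt <- trial_type_of(tr$sequence, tr$position)
  sel <- matrix(NA_integer_, n_per_type, 8L)
  for (b in 1:8) {
    pool <- usable[tt[usable] == b]
    if (length(pool) < n_per_type)
      sg_stop("session ", session$session_id, ": only ", length(pool),
              " correct analyzable trials of type ", b,
              " (need ", n_per_type, ")")
    sel[, b] <- with_seed(derive_seed(seed, "select", session$session_id, b),
                          sort(sample(pool, n_per_type)))
  }
  sel
}

#' Build per-epoch trial-by-unit rate matrices
#'
#' For every session, a seeded random selection of `n_per_type` correct
#' trials is made from each of the 8 trial types; the post-event mean rates
#' of all units are assembled, per epoch, into a matrix with
#' `8 * n_per_type` rows (trials, blocked by type) and one column per unit.
#' Units from different sessions are concatenated column-wise, aligned by
#' (trial type, selection slot).
#'
#' @param sessions List of `"session_record"` objects (or a single one).
#' @param n_per_type Correct trials selected per trial type (default 30).
#' @param seed Integer master seed for the per-session selections.
#' @param params A [binning_params()] object.
#' @param rates Optional list of precomputed [epoch_rates()] results,
#'   parallel to `sessions`.
#' @return Named list (one per epoch) of `"epoch_rate_matrix"` objects:
#'   `epoch`, `rates` (matrix), `labels` (per-row data.frame with
#'   `trial_type`, `sequence`, `position`, `rewarded`, `slot`), `unit_info`
#'   (per-column session and unit id), `n_per_type`, `seed`.
#' @export
build_rate_matrices <- function(sessions, n_per_type = 30, seed = 1,
                                params = binning_params(), rates = NULL) {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  if (is.null(rates)) rates <- lapply(sessions, epoch_rates, params = params)
  n_row <- 8L * n_per_type
  types <- rep(1:8, each = n_per_type)
  labels <- data.frame(trial_type = types,
                       sequence = type_sequence(types),
                       position = type_position(types),
                       rewarded = type_position(types) %in% c("P1", "P4"),
                       slot = rep(seq_len(n_per_type), 8L))
  blocks <- vector("list", length(sessions))
  unit_info <- NULL
  for (s in seq_along(sessions)) {
    sel <- select_trials(sessions[[s]], rates[[s]]$analyzable, n_per_type, seed)
    mr <- rates[[s]]$mean_rates
    blk <- array(NA_real_, c(n_row, dim(mr)[1], 9L))
    for (b in 1:8) {
      rows <- (b - 1L) * n_per_type + seq_len(n_per_type)
      blk[rows, , ] <- aperm(mr[, sel[, b], , drop = FALSE], c(2, 1, 3))
    }
    blocks[[s]] <- blk
    unit_info <- rbind(unit_info, data.frame(
      session = sessions[[s]]$session_id,
      unit_id = vapply(sessions[[s]]$units, `[[`, "", "unit_id"),
      group_label = vapply(sessions[[s]]$units, `[[`, "", "group_label")))
  }
  out <- vector("list", 9L)
  names(out) <- EPOCHS
  for (e in 1:9) {
    m <- do.call(cbind, lapply(blocks, function(b) b[, , e, drop = TRUE]))
    m <- matrix(m, nrow = n_row)
    out[[e]] <- structure(list(epoch = EPOCHS[e], rates = m, labels = labels,
                               unit_info = unit_info,
                               n_per_type = n_per_type, seed = seed),
                          class = "epoch_rate_matrix")
  }
  out
}

#' Build the units x time x trials tensor for CP decomposition
#'
#' Stacks smoothed per-bin firing rates into a three-way array with
#' `T = 9 epochs * 8 bins = 72` time samples. The trial mode is blocked
#' position-major (P1 trials first, both sequences, then P2, ...), 40 trials
#' per (position, sequence) block for complete sessions, giving `K = 320`;
#' rewarded trials occupy trial indices 1--80 and 241--320. Each unit is
#' soft-normalized by its maximum rate + 1 Hz across the tensor.
#'
#' @param sessions List of complete `"session_record"`s (every trial type
#'   present `n_repeats_per_sequence` times and analyzable).
#' @param params A [binning_params()] object.
#' @param normalize Apply the per-unit soft max normalization?
#' @param rates Optional precomputed [epoch_rates()] list.
#' @return Object of class `"trial_tensor"`: `data` (N x 72 x K array),
#'   `trial_labels` (per-slice data.frame), `epoch_of_bin` (length-72 epoch
#'   labels), `unit_info`, `normalize`.
#' @export
build_trial_tensor <- function(sessions, params = binning_params(),
                               normalize = TRUE, rates = NULL) {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  if (is.null(rates)) rates <- lapply(sessions, epoch_rates, params = params)
  nrep <- sessions[[1]]$task$n_repeats_per_sequence
  K <- 8L * nrep
  Tlen <- 9L * params$n_bins
  slice_order <- function(ses) {
    tr <- ses$trials
    tt <- trial_type_of(tr$sequence, tr$position)
    unlist(lapply(seq_len(8L), function(b) {
      which(type_position(tt) == TENSOR_BLOCK_ORDER$position[b] &
              type_sequence(tt) == TENSOR_BLOCK_ORDER$sequence[b])
    }))
  }
  blocks <- Map(function(ses, rt) {
    if (nrow(ses$trials) != K || !all(rt$analyzable))
      sg_stop("session ", ses$session_id,
              ": trial tensor requires a complete, fully analyzable session")
    rt$bin_rates[, slice_order(ses), , drop = FALSE]
  }, sessions, rates)
  N <- sum(vapply(blocks, function(b) dim(b)[1], 0L))
  X <- array(0, c(N, Tlen, K))
  at <- 0L
  for (b in blocks) {
    X[at + seq_len(dim(b)[1]), , ] <- aperm(b, c(1, 3, 2))
    at <- at + dim(b)[1]
  }
  if (normalize) {
    mx <- apply(X, 1, max)
    X <- X / (mx + 1)
  }
  lab_block <- rep(seq_len(8L), each = nrep)
  trial_labels <- data.frame(
    block = lab_block,
    position = TENSOR_BLOCK_ORDER$position[lab_block],
    sequence = TENSOR_BLOCK_ORDER$sequence[lab_block],
    rewarded = TENSOR_BLOCK_ORDER$position[lab_block] %in% c("P1", "P4"),
    trial_type = trial_type_of(TENSOR_BLOCK_ORDER$sequence[lab_block],
                               TENSOR_BLOCK_ORDER$position[lab_block]),
    # chronological index of each slice in its session (first session's
    # ordering): the time axis for trial-factor MI
    chron_index = slice_order(sessions[[1]]))
  unit_info <- do.call(rbind, lapply(sessions, function(s) data.frame(
    session = s$session_id,
    unit_id = vapply(s$units, `[[`, "", "unit_id"))))
  structure(list(data = X, trial_labels = trial_labels,
                 epoch_of_bin = rep(EPOCHS, each = params$n_bins),
                 unit_info = unit_info, normalize = normalize),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("<trial_tensor> ", d[1], " units x ", d[2], " time bins x ",
      d[3], " trials\n", sep = "")
  invisible(x)
}

#' Per-unit 120 x 9 epoch feature matrix for position decoding
#'
#' For one sequence, selects `n_per_type` correct trials per position and
#' returns, per unit, the trials-by-epochs matrix of post-event mean rates
#' (120 x 9 at the default 30 trials per type). Multi-unit features are the
#' column-wise concatenation over units.
#'
#' @param session A `"session_record"`.
#' @param sequence `"S1"` or `"S2"`.
#' @param n_per_type Trials per position (default 30).
#' @param seed Integer seed for the selection.
#' @param params A [binning_params()] object.
#' @param rates Optional precomputed [epoch_rates()] result for the session.
#' @return List: `features` (trials x (9 * n_units) matrix, unit-major
#'   column blocks), `per_unit` (list of trials x 9 matrices), `position`
#'   (per-row labels), `slot` (within-position selection index).
#' @export
position_feature_matrix <- function(session, sequence, n_per_type = 30,
                                    seed = 1, params = binning_params(),
                                    rates = NULL) {
  if (is.null(rates)) rates <- epoch_rates(session, params)
  tr <- session$trials
  usable <- which(rates$analyzable & tr$correct %in% TRUE &
                    tr$sequence == sequence)
  sel <- integer(0)
  for (p in POSITIONS) {
    pool <- usable[tr$position[usable] == p]
    if (length(pool) < n_per_type)
      sg_stop("session ", session$session_id, ": only ", length(pool),
              " usable ", sequence, "-", p, " trials (need ", n_per_type, ")")
    sel <- c(sel, with_seed(derive_seed(seed, "posfeat", session$session_id,
                                        sequence, p),
                            sort(sample(pool, n_per_type))))
  }
  per_unit <- lapply(seq_along(session$units), function(u)
    rates$mean_rates[u, sel, , drop = TRUE])
  per_unit <- lapply(per_unit, function(m) matrix(m, ncol = 9L,
                                                  dimnames = list(NULL, EPOCHS)))
  list(features = do.call(cbind, per_unit), per_unit = per_unit,
       position = rep(POSITIONS, each = n_per_type),
       slot = rep(seq_len(n_per_type), 4L))
}
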