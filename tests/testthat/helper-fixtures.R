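# Shared fixtures, built once per test run and memoized. Sizes are kept
# small: short sessions (few repeats) wherever the analysis allows it, and
# full-length sessions only where a complete 40-repeat session is required.

.fx <- new.env(parent = emptyenv())

# internal helpers used when building fixtures
with_seed <- stategen:::with_seed
type_sequence <- stategen:::type_sequence
type_position <- stategen:::type_position

fixture <- function(name, build) {
  if (!exists(name, .fx)) assign(name, build(), .fx)
  get(name, .fx)
}

# Short task: 6 repeats per sequence (48 trials).
short_task <- function(n_rep = 6L) task_config(n_repeats_per_sequence = n_rep)

# Small complete session from a template, short task.
fixture_group <- function(template = "compressed", n_units = 4, n_rep = 6L,
                          seed = 101, ...) {
  key <- paste("grp", template, n_units, n_rep, seed, sep = "_")
  fixture(key, function()
    simulate_group(population_template(template, n_units = n_units, ...),
                   n_sessions = 1, seed = seed, task = short_task(n_rep)))
}

# Full-scale study groups (complete 40-repeat sessions) shared between the
# acceptance checks and the heavier property tests. The compressed group is
# at the 300-unit study scale; the differentiated comparison group uses 150
# units (decoding subsamples 100-unit pseudoensembles from either).
study_group <- function(template, seed = 11) {
  n_units <- if (template == "compressed") 300 else 150
  key <- paste("study", template, seed, sep = "_")
  fixture(key, function()
    simulate_group(population_template(template, n_units = n_units),
                   n_sessions = 1, seed = seed))
}

study_rates <- function(template, seed = 11) {
  key <- paste("studyrates", template, seed, sep = "_")
  fixture(key, function()
    lapply(study_group(template, seed)$sessions, epoch_rates))
}

study_matrices <- function(template, seed = 11) {
  key <- paste("studyrm", template, seed, sep = "_")
  fixture(key, function()
    build_rate_matrices(study_group(template, seed)$sessions, 30, seed = 21,
                        rates = study_rates(template, seed)))
}

study_tensor <- function(template, seed = 11) {
  key <- paste("studytt", template, seed, sep = "_")
  fixture(key, function()
    build_trial_tensor(study_group(template, seed)$sessions,
                       rates = study_rates(template, seed)))
}

# The 100-restart rank-10 ensemble on the compressed study tensor (the
# heaviest shared fixture; also reused by the MI recovery checks).
study_ensemble <- function(template, n_restarts = 100, seed = 11) {
  key <- paste("studyens", template, n_restarts, seed, sep = "_")
  fixture(key, function()
    restart_ensemble(study_tensor(template, seed), 10,
                     n_restarts = n_restarts, seed = 31))
}

# Behavior-only session (no units): cheap, used for behavior statistics.
behavior_session <- function(template, seed, n_rep = 40L) {
  tpl <- population_template(template, n_units = 0)
  task <- task_config(n_repeats_per_sequence = n_rep)
  sched <- make_task_schedule(task, seed)
  trials <- simulate_behavior(sched, tpl$behavior, seed, task)
  session_record(sprintf("beh_%s_%d", template, seed), task, trials)
}

# Hand-built epoch rate matrix: gen(sequence, position) returns the mean
# rate; Gaussian noise sd `noise` on top; n_units columns.
synthetic_rate_matrix <- function(gen, n_per_type = 10, n_units = 4,
                                  noise = 1, seed = 1, epoch = "Odor") {
  types <- rep(1:8, each = n_per_type)
  labels <- data.frame(trial_type = types,
                       sequence = type_sequence(types),
                       position = type_position(types),
                       rewarded = type_position(types) %in% c("P1", "P4"),
                       slot = rep(seq_len(n_per_type), 8))
  rates <- with_seed(seed, {
    m <- vapply(seq_len(n_units), function(u)
      gen(labels$sequence, labels$position, u) +
        stats::rnorm(nrow(labels), 0, noise), numeric(nrow(labels)))
    matrix(m, nrow(labels))
  })
  structure(list(epoch = epoch, rates = rates, labels = labels,
                 unit_info = data.frame(session = "syn",
                                        unit_id = paste0("u", seq_len(n_units)),
                                        group_label = "syn"),
                 n_per_type = n_per_type, seed = seed),
            class = "epoch_rate_matrix")
}

# Same generator replicated over all 9 epochs.
synthetic_rate_matrices <- function(gen, ...) {
  out <- lapply(EPOCHS, function(e) synthetic_rate_matrix(gen, ..., epoch = e))
  names(out) <- EPOCHS
  out
}

# Random CP model with unit-norm factor columns.
random_cp_model <- function(dims, rank, seed, nonneg = TRUE) {
  fac <- with_seed(seed, lapply(dims, function(n) {
    A <- if (nonneg) matrix(stats::runif(n * rank), n, rank)
    else matrix(stats::rnorm(n * rank), n, rank)
    sweep(A, 2, sqrt(colSums(A^2)), `/`)
  }))
  lambda <- with_seed(seed + 1, sort(stats::runif(rank, 0.5, 2),
                                     decreasing = TRUE))
  structure(list(rank = as.integer(rank),
                 factors = list(unit = fac[[1]], time = fac[[2]],
                                trial = fac[[3]]),
                 lambda = lambda, error = NA_real_,
                 error_history = numeric(0), iterations = 0L,
                 converged = TRUE, nonneg = nonneg, seed = seed),
            class = "cp_model")
}

# Rank-R tensor from factor lists (list of 3 matrices) + optional noise.
tensor_from_factors <- function(fac, lambda = NULL, noise = 0, seed = 1) {
  R <- ncol(fac[[1]])
  if (is.null(lambda)) lambda <- rep(1, R)
  X <- array(0, vapply(fac, nrow, 0L))
  for (r in seq_len(R))
    X <- X + lambda[r] * outer(outer(fac[[1]][, r], fac[[2]][, r]),
                               fac[[3]][, r])
  if (noise > 0)
    X <- X + with_seed(seed, array(stats::rnorm(length(X), 0,
                                                noise * stats::sd(X)),
                                   dim(X)))
  X
}

# Exhaustive-permutation reference for the similarity score (independent of
# the Hungarian implementation): maximizes total congruence over all R!
# matchings.
similarity_bruteforce <- function(a, b) {
  R <- a$rank
  C <- stategen:::congruence_matrix(a, b)
  perms <- do.call(rbind, combinat_perms(seq_len(R)))
  best <- -Inf; best_p <- NULL
  for (i in seq_len(nrow(perms))) {
    tot <- sum(C[cbind(seq_len(R), perms[i, ])])
    if (tot > best) { best <- tot; best_p <- perms[i, ] }
  }
  cg <- C[cbind(seq_len(R), best_p)]
  w <- (a$lambda / sum(a$lambda) + b$lambda[best_p] / sum(b$lambda)) / 2
  sum(w * cg)
}

combinat_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(combinat_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# Congruence of each column of A with the matched column of B, after
# optimal matching on the product-congruence (used for planted-factor
# recovery checks).
factor_congruence <- function(fit, fac_true) {
  true_model <- structure(list(
    rank = ncol(fac_true[[1]]),
    factors = list(unit = fac_true[[1]], time = fac_true[[2]],
                   trial = fac_true[[3]]),
    lambda = rep(1, ncol(fac_true[[1]]))), class = "cp_model")
  C <- stategen:::congruence_matrix(true_model, fit)
  perm <- stategen:::assignment_min(-C)
  per_mode <- vapply(seq_len(ncol(fac_true[[1]])), function(r) {
    vapply(1:3, function(m)
      abs(sum(fac_true[[m]][, r] * fit$factors[[m]][, perm[r]])) /
        sqrt(sum(fac_true[[m]][, r]^2) * sum(fit$factors[[m]][, perm[r]]^2)),
      0)
  }, numeric(3))
  per_mode   # 3 x R matrix of |cosine| per mode
}
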