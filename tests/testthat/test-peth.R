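test_that("epoch anchors follow the event rules for each trial outcome", {
  # non-rewarded correct no-go: Choice = poke_out + 2, then 0.7 s steps
  t_nogo <- list(light_on = 5.0, poke_in = 8.2, odor_on = 8.7,
                 poke_out = 10.0, well_entry = NA, reward_time = NA,
                 rewarded = FALSE)
  a <- anchor_epochs(t_nogo)
  expect_equal(unname(a[c("ITI-a", "Light", "Poke", "Odor", "Unpoke")]),
               c(4.3, 5.0, 8.2, 8.7, 10.0))
  expect_equal(unname(a[c("Choice", "Outcome", "postOut", "ITI-b")]),
               c(12.0, 12.7, 13.4, 14.1))

  # rewarded correct go: Choice = well entry, Outcome = reward delivery
  t_go <- list(light_on = 5.0, poke_in = 8.2, odor_on = 8.7,
               poke_out = 10.0, well_entry = 13.5, reward_time = 15.0,
               rewarded = TRUE)
  b <- anchor_epochs(t_go)
  expect_equal(unname(b[c("Choice", "Outcome", "postOut", "ITI-b")]),
               c(13.5, 15.0, 15.7, 16.4))
  expect_true(all(diff(b) >= 0))

  # missing required timestamp flags the trial unanalyzable
  t_miss <- t_nogo; t_miss$poke_in <- NA
  expect_null(anchor_epochs(t_miss))
})

test_that("spike binning uses half-open 100 ms bins around the anchor", {
  p <- binning_params()
  expect_equal(p$n_bins, 8L)
  expect_equal(bin_spikes(numeric(0), 10, p), rep(0L, 8))
  # spike exactly at the anchor falls in the first post-anchor bin (3rd bin)
  expect_equal(bin_spikes(10, 10, p), c(0, 0, 1, 0, 0, 0, 0, 0))
  # right edge excluded, left edge included
  expect_equal(bin_spikes(10.6, 10, p), rep(0L, 8))
  expect_equal(bin_spikes(9.8, 10, p), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(bin_spikes(c(9.95, 10.05, 10.05, 10.55), 10, p),
               c(0, 1, 2, 0, 0, 0, 0, 1))
})

test_that("Gaussian smoothing matches direct convolution and conserves mass", {
  p <- binning_params()
  counts <- c(0, 0, 0, 0, 10, 0, 0, 0)
  sm <- smooth_counts(counts, p)
  # independent oracle: direct convolution with the renormalized kernel
  kern <- exp(-(-1:1)^2 / (2 * 0.5^2)); kern <- kern / sum(kern)
  direct <- sapply(1:8, function(i) {
    acc <- 0
    for (k in -1:1) if (i - k >= 1 && i - k <= 8)
      acc <- acc + kern[k + 2] * counts[i - k]
    acc / p$bin_width
  })
  expect_equal(sm, direct, tolerance = 1e-12)
  # center impulse: symmetric bump, total mass conserved
  expect_equal(sum(sm) * p$bin_width, 10)
  expect_equal(sm[4], sm[6])
  expect_gt(sm[5], sm[4])

  # constant input stays constant in the interior
  smu <- smooth_counts(rep(3, 8), p)
  expect_equal(smu[2:7], rep(30, 6))
  expect_lt(smu[1], 30)   # edge truncation loses mass

  # sigma -> 0 reduces to counts / bin width
  p0 <- binning_params(smooth_sigma = 0)
  expect_equal(smooth_counts(counts, p0), counts / 0.1)
})

test_that("epoch mean rate averages the 100-600 ms post-event bins", {
  expect_equal(epoch_mean_rate(rep(4, 8)), 4)
  expect_equal(epoch_mean_rate(c(0, 0, 0, 10, 10, 10, 10, 10)), 10)
  expect_equal(epoch_mean_rate(c(9, 9, 9, 0, 0, 0, 0, 0)), 0)
})

test_that("epoch mean rate is an unbiased estimate for Poisson spiking", {
  # constant-rate unit over a session; estimate pooled across trials/epochs
  task <- short_task(6)
  sched <- make_task_schedule(task, 3)
  trials <- simulate_behavior(sched, behavior_profile(accuracy = 1), 3, task)
  r <- 7
  ses <- session_record("pois", task, trials, list(
    simulate_unit(unit_tuning_profile(baseline_rate = r), trials, seed = 4,
                  unit_id = "u1")))
  er <- epoch_rates(ses)
  est <- er$mean_rates[1, , ]
  n_eff <- sum(!is.na(est))
  # each estimate is a 0.5 s Poisson count average: var ~ r / 0.5 per cell
  se <- sqrt(r / 0.5 / n_eff)
  expect_lt(abs(mean(est, na.rm = TRUE) - r), 3 * se)
})

test_that("rate matrices have the standard layout and reproducible selection", {
  g <- fixture_group("compressed", n_units = 4, n_rep = 6)
  rm6 <- build_rate_matrices(g$sessions, n_per_type = 5, seed = 3)
  expect_named(rm6, EPOCHS)
  m <- rm6[["Odor"]]
  expect_equal(dim(m$rates), c(40L, 4L))
  expect_equal(m$labels$trial_type, rep(1:8, each = 5))
  expect_true(all(m$labels$rewarded == (m$labels$position %in% c("P1", "P4"))))

  rm1 <- build_rate_matrices(g$sessions, n_per_type = 1, seed = 3)
  expect_equal(nrow(rm1[["Odor"]]$rates), 8L)

  # reproducible from the seed
  again <- build_rate_matrices(g$sessions, n_per_type = 5, seed = 3)
  expect_identical(again[["Choice"]]$rates, rm6[["Choice"]]$rates)

  # insufficient correct trials: error names session and type
  expect_error(build_rate_matrices(g$sessions, n_per_type = 7, seed = 3),
               "compressed01.*type")
})

test_that("unit columns only permute when session order changes", {
  g <- fixture_group("compressed", n_units = 3, n_rep = 6)
  g2 <- simulate_group(population_template("compressed", n_units = 2),
                       1, seed = 77, task = short_task(6))
  g2$sessions[[1]]$session_id <- "other"
  g2$sessions[[1]]$units <- lapply(g2$sessions[[1]]$units, function(u) {
    u$unit_id <- paste0("other_", u$unit_id); u
  })
  ab <- build_rate_matrices(c(g$sessions, g2$sessions), 5, seed = 3)
  ba <- build_rate_matrices(c(g2$sessions, g$sessions), 5, seed = 3)
  perm <- match(ab[["Odor"]]$unit_info$unit_id, ba[["Odor"]]$unit_info$unit_id)
  expect_identical(ab[["Odor"]]$rates, ba[["Odor"]]$rates[, perm])
})

test_that("trial tensor has the 72-bin x blocked-trial layout", {
  g <- fixture_group("compressed", n_units = 4, n_rep = 6)
  tt <- build_trial_tensor(g$sessions)
  expect_s3_class(tt, "trial_tensor")
  expect_equal(dim(tt$data), c(4L, 72L, 48L))
  expect_equal(tt$epoch_of_bin, rep(EPOCHS, each = 8))
  # blocks are position-major: rewarded trials first and last quarter
  expect_equal(tt$trial_labels$position, rep(POSITIONS, each = 12))
  expect_equal(tt$trial_labels$rewarded,
               rep(c(TRUE, FALSE, FALSE, TRUE), each = 12))
  expect_equal(tt$trial_labels$sequence, rep(rep(SEQUENCES, each = 6), 4))
  # chronological index covers every trial exactly once
  expect_setequal(tt$trial_labels$chron_index, seq_len(48))

  # per-unit soft normalization bounds entries below 1
  expect_true(all(tt$data >= 0 & tt$data < 1))
  raw <- build_trial_tensor(g$sessions, normalize = FALSE)
  mx <- apply(raw$data, 1, max)
  expect_equal(raw$data / (mx + 1), tt$data, tolerance = 1e-12)

  # incomplete session rejected
  broken <- g$sessions[[1]]
  broken$trials <- broken$trials[-1, ]
  expect_error(build_trial_tensor(list(broken)), "complete")
})

test_that("position feature matrices are trials x epochs per unit", {
  g <- fixture_group("compressed", n_units = 3, n_rep = 6)
  pf <- position_feature_matrix(g$sessions[[1]], "S1", n_per_type = 5,
                                seed = 2)
  expect_equal(dim(pf$per_unit[[1]]), c(20L, 9L))
  expect_equal(dim(pf$features), c(20L, 27L))
  expect_equal(pf$position, rep(POSITIONS, each = 5))
  # default selection count gives the standard 120-row matrix
  expect_error(position_feature_matrix(g$sessions[[1]], "S1", 30, seed = 2),
               "usable")
})
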