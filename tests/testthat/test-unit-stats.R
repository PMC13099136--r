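test_that("sequence selectivity detects separation and respects its level", {
  # fully separated samples: rank-sum p far below any usual threshold
  res <- sequence_selectivity(rep(10, 30) + runif(30) * 0.01, rep(0, 30) +
                                runif(30) * 0.01)
  expect_true(res$selective)
  expect_lt(res$p, 1e-9)

  # identical constant rates: not selective
  res0 <- sequence_selectivity(rep(5, 10), rep(5, 10))
  expect_false(res0$selective)

  expect_error(sequence_selectivity(1:4, 1:10), ">= 5")

  # type-I calibration: flag rate ~ alpha under the null
  flags <- with_seed(42, vapply(1:1000, function(i)
    sequence_selectivity(rnorm(30, 5), rnorm(30, 5))$selective, TRUE))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(flags) - 0.05), 3 * se)
})

test_that("selectivity tables and fraction curves cover the 36 cells", {
  # synthetic matrices: units selective only at P4 (rate differs by sequence)
  gen <- function(sequence, position, u)
    10 + 6 * (position == "P4") * (sequence == "S1")
  rms <- synthetic_rate_matrices(gen, n_per_type = 10, n_units = 6,
                                 noise = 1, seed = 3)
  tab <- selectivity_table(rms)
  expect_equal(nrow(tab), 9 * 4 * 6)
  frac <- selectivity_fraction_curve(tab)
  expect_equal(nrow(frac), 36L)
  expect_true(all(frac$fraction[frac$position == "P4"] > 0.9))
  expect_lt(mean(frac$fraction[frac$position != "P4"]), 0.2)

  # all-null table gives all-zero fractions
  tab0 <- tab; tab0$selective <- FALSE
  expect_true(all(selectivity_fraction_curve(tab0)$fraction == 0))
})

test_that("chi-squared group comparison matches the hand formula", {
  # equal proportions: statistic exactly 0
  eq <- compare_fractions(50, 1000, 50, 1000)
  expect_equal(eq$chisq, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)

  # brute-force oracle: sum (O - E)^2 / E on the 2x2 table
  o <- matrix(c(100, 800, 50, 900), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi_oracle <- sum((o - e)^2 / e)
  got <- compare_fractions(100, 900, 50, 950)
  expect_equal(got$chisq, chi_oracle, tolerance = 1e-9)
  expect_equal(got$p, stats::pchisq(chi_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  # symmetric in the group order
  swapped <- compare_fractions(50, 950, 100, 900)
  expect_equal(swapped$chisq, got$chisq)

  # zero margin handled
  expect_message(z <- compare_fractions(0, 100, 0, 100), "zero margin")
  expect_equal(z$p, 1)
})

test_that("two-way ANOVA matches closed-form sums of squares", {
  seqs <- rep(rep(SEQUENCES, each = 12), 4)
  poss <- rep(POSITIONS, each = 24)
  # hand-computable balanced case with known effects + noise
  y <- with_seed(9, 2 + 1.5 * (seqs == "S2") + 0.8 * as.integer(factor(poss)) +
                   rnorm(96, 0, 1))
  res <- two_way_anova_unit(y, seqs, poss)

  # closed-form oracle from cell/marginal means
  gm <- mean(y)
  ms <- tapply(y, seqs, mean); mp <- tapply(y, poss, mean)
  mc <- tapply(y, interaction(seqs, poss), mean)
  ss_s <- 48 * sum((ms - gm)^2)
  ss_p <- 24 * sum((mp - gm)^2)
  cell_seq <- tapply(seqs, interaction(seqs, poss), `[`, 1)
  cell_pos <- tapply(poss, interaction(seqs, poss), `[`, 1)
  ss_i <- 12 * sum((mc - ms[cell_seq] - mp[cell_pos] + gm)^2)
  ss_e <- sum((y - mc[interaction(seqs, poss)])^2)
  expect_equal(res$F[1], (ss_s / 1) / (ss_e / 88), tolerance = 1e-8)
  expect_equal(res$F[2], (ss_p / 3) / (ss_e / 88), tolerance = 1e-8)
  expect_equal(res$F[3], (ss_i / 3) / (ss_e / 88), tolerance = 1e-8)
  expect_equal(res$eta_p2[1], ss_s / (ss_s + ss_e), tolerance = 1e-8)

  # identical cells: all F = 0
  flat <- two_way_anova_unit(rep(3, 96), seqs, poss)
  expect_equal(flat$F, rep(0, 3))

  # planted crossover interaction is detected at 30 trials/cell
  seqs30 <- rep(rep(SEQUENCES, each = 30), 4)
  poss30 <- rep(POSITIONS, each = 60)
  cross <- with_seed(4, 5 + 5 * (seqs30 == "S1") * (poss30 == "P1") -
                       5 * (seqs30 == "S2") * (poss30 == "P1") + rnorm(240))
  expect_lt(two_way_anova_unit(cross, seqs30, poss30)$p[3], 0.01)

  # additive effects: interaction false-positive rate ~ alpha
  ps <- with_seed(6, vapply(1:200, function(i) {
    yy <- 1 + (seqs == "S1") + as.integer(factor(poss)) + rnorm(96)
    two_way_anova_unit(yy, seqs, poss)$p[3]
  }, 0))
  expect_lt(abs(mean(ps < 0.05) - 0.05) , 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("preferred-position correlation recovers planted preferences", {
  # units prefer a fixed position, identical on both sequences -> r = 1
  gen_same <- function(sequence, position, u)
    10 + 8 * (position == POSITIONS[(u %% 4) + 1])
  rms <- synthetic_rate_matrices(gen_same, n_per_type = 8, n_units = 8,
                                 noise = 0.5, seed = 5)
  pp <- preferred_position_analysis(rms, alpha = 0.01)
  expect_gt(pp$n, 5)
  expect_equal(pp$r, 1)

  # independent preferences across sequences -> r near 0
  gen_ind <- function(sequence, position, u) {
    pref <- ifelse(sequence == "S1", POSITIONS[(u %% 4) + 1],
                   POSITIONS[((u + 1) %% 4) + 1])
    10 + 8 * (position == pref)
  }
  rms2 <- synthetic_rate_matrices(gen_ind, n_per_type = 8, n_units = 8,
                                  noise = 0.5, seed = 6)
  pp2 <- preferred_position_analysis(rms2)
  expect_lt(abs(pp2$r), 0.6)

  # too few pairs: correlation reported absent
  gen_flat <- function(sequence, position, u) 10
  rms3 <- synthetic_rate_matrices(gen_flat, n_per_type = 8, n_units = 2,
                                  noise = 1, seed = 7)
  pp3 <- preferred_position_analysis(rms3)
  expect_true(is.na(pp3$r))
})

test_that("Fisher r-to-z comparison matches the closed form", {
  same <- fisher_r_to_z(0.4, 50, 0.4, 80)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  got <- fisher_r_to_z(0.5, 103, 0.0, 103)
  expect_equal(got$z, atanh(0.5) * sqrt(50), tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(got$z)), tolerance = 1e-12)

  # antisymmetric in the group order
  rev <- fisher_r_to_z(0.0, 103, 0.5, 103)
  expect_equal(rev$z, -got$z)
  expect_equal(rev$p, got$p)

  expect_error(fisher_r_to_z(1, 10, 0.5, 10), "diverges")
  expect_error(fisher_r_to_z(0.5, 3, 0.5, 10), "n > 3")
})

test_that("interaction prevalence counts significant units", {
  gen <- function(sequence, position, u) {
    if (u <= 3) 10 + 6 * (sequence == "S1") * (position == "P1") else 10
  }
  rm1 <- synthetic_rate_matrix(gen, n_per_type = 20, n_units = 6,
                               noise = 1, seed = 8)
  ip <- interaction_prevalence(rm1)
  expect_equal(nrow(ip$per_unit), 6L)
  expect_gte(ip$n_significant, 3L)
  expect_true(all(ip$per_unit$p[1:3] < 0.01))
})
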