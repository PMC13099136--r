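test_that("pseudoensembles preserve per-type rate marginals and decorrelate units", {
  gen <- function(sequence, position, u) 10
  rm1 <- synthetic_rate_matrix(gen, n_per_type = 8, n_units = 3, noise = 2,
                               seed = 4)
  # make units 2 and 3 perfectly correlated copies
  rm1$rates[, 3] <- rm1$rates[, 2]
  pe <- assemble_pseudoensembles(rm1, 40, seed = 5)
  expect_length(pe, 40L)
  lb <- rm1$labels
  for (b in c(1, 5)) {
    rows <- lb$trial_type == b
    for (u in 1:3)
      expect_setequal(pe[[7]][rows, u], rm1$rates[rows, u])
  }
  # shuffling removed the across-unit trial correlation (on average)
  cors <- vapply(pe, function(x) cor(x[, 2], x[, 3]), 0)
  expect_lt(abs(mean(cors)), 0.15)
  expect_equal(assemble_pseudoensembles(rm1, 3, seed = 5)[[2]], pe[[2]])

  # a single unit loses nothing: marginals are the full description
  rm_one <- rm1; rm_one$rates <- rm1$rates[, 1, drop = FALSE]
  p1 <- assemble_pseudoensembles(rm_one, 2, seed = 6)
  expect_setequal(p1[[1]][lb$trial_type == 2, 1],
                  rm_one$rates[lb$trial_type == 2, 1])
})

test_that("the linear decoder solves separable problems like a max-margin rule", {
  # two linearly separable clouds: perfect training accuracy
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  y <- rep(c("a", "b"), each = 20)
  dec <- linear_decoder_fit(x, y)
  expect_equal(mean(linear_decoder_predict(dec, x) == y), 1)

  # fixed small instance with a known maximum-margin boundary (x1 = 1):
  # the two closest points per class pin the separator midway
  x8 <- matrix(c(0, 0,  0, 1,  0.2, 0.5,  0, 0.25,
                 2, 0,  2, 1,  1.8, 0.5,  2, 0.75), ncol = 2, byrow = TRUE)
  y8 <- rep(c("a", "b"), each = 4)
  dec8 <- linear_decoder_fit(x8, y8, cost = 1e3)
  probe <- matrix(c(0.85, 0.5, 1.15, 0.5), ncol = 2, byrow = TRUE)
  expect_equal(linear_decoder_predict(dec8, probe), c("a", "b"))

  # multiclass one-vs-rest: class means at simplex corners so every
  # class is linearly separable from the rest
  x3 <- rbind(cbind(rnorm(10, 0), rnorm(10, 0)),
              cbind(rnorm(10, 6), rnorm(10, 0)),
              cbind(rnorm(10, 0), rnorm(10, 6)))
  y3 <- rep(c("P1", "P2", "P3"), each = 10)
  d3 <- linear_decoder_fit(x3, y3)
  expect_equal(mean(linear_decoder_predict(d3, x3) == y3), 1)

  expect_error(linear_decoder_fit(x, rep("a", 40)), "single class")
})

test_that("leave-one-out accuracy separates signal from chance", {
  with_seed(10, {
    x_sep <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 5), 20))
    y <- rep(c("S1", "S2"), each = 20)
    expect_equal(loo_accuracy(x_sep, y, n_reps = 20, seed = 1), 1)

    # planted 2 SD mean separation, 50 units, 30 trials/class
    x_sig <- rbind(matrix(rnorm(30 * 50, 0), 30),
                   matrix(rnorm(30 * 50, 2), 30))
    y30 <- rep(c("S1", "S2"), each = 30)
    expect_gt(loo_accuracy(x_sig, y30, n_reps = 30, seed = 2), 0.9)

    # label-independent features: inside the shuffled null band
    x_null <- matrix(rnorm(40 * 10), 40)
    acc <- loo_accuracy(x_null, y, n_reps = 30, seed = 3)
    nl <- shuffled_null(x_null, y, n_shuffles = 60, seed = 4, n_reps = 10)
    expect_gte(acc, nl$ci[1] - 0.05)
    expect_lte(acc, nl$ci[2] + 0.05)
    # null centered on chance
    expect_lt(abs(nl$mean - 0.5), 3 * sd(nl$dist) / sqrt(60) + 0.02)
    expect_warning(shuffled_null(x_null, y, n_shuffles = 2, n_reps = 2),
                   "degenerate")
  })
})

test_that("S1-vs-S2 decoding stays at chance for duplicated-class inputs", {
  # both "sequences" drawn from the identical distribution
  gen <- function(sequence, position, u) 8
  rms <- synthetic_rate_matrices(gen, n_per_type = 10, n_units = 12,
                                 noise = 2, seed = 20)
  d <- s1_vs_s2_decoding(rms, "P2", "Odor", n_pseudo = 10, n_shuffles = 40,
                         n_reps = 10, seed = 3)
  expect_false(d$above_null)
  expect_lt(abs(d$accuracy - 0.5), 0.15)
  expect_equal(d$chance, 0.5)

  # planted sequence signal at P4 is detected
  gen_sig <- function(sequence, position, u)
    8 + 5 * (position == "P4") * (sequence == "S1")
  rms_sig <- synthetic_rate_matrices(gen_sig, n_per_type = 10, n_units = 12,
                                     noise = 2, seed = 21)
  d_sig <- s1_vs_s2_decoding(rms_sig, "P4", "Odor", n_pseudo = 10,
                             n_shuffles = 40, n_reps = 10, seed = 3)
  expect_true(d_sig$above_null)
  expect_gt(d_sig$accuracy, 0.9)

  expect_error(s1_vs_s2_decoding(rms, "P1", "Odor", ensemble_size = 99),
               "available units")
})

test_that("ensemble size curves grow with informative populations", {
  gen_sig <- function(sequence, position, u)
    8 + 1.2 * (sequence == "S1")
  rms <- synthetic_rate_matrices(gen_sig, n_per_type = 10, n_units = 60,
                                 noise = 2, seed = 22)
  cur <- ensemble_size_curve(rms, "P1", "Odor", sizes = c(5, 60),
                             n_pseudo = 12, n_reps = 10, seed = 5)
  per <- attr(cur, "per_pseudo")
  # paired over pseudoensembles, the large ensemble wins
  expect_gt(mean(per[, 2] >= per[, 1]), 0.5)
  expect_gt(cur$accuracy[2], cur$accuracy[1])

  # the full-ensemble size equals an unsubsampled decode of the same stream
  full <- s1_vs_s2_decoding(rms, "P1", "Odor", ensemble_size = NULL,
                            n_pseudo = 12, n_shuffles = 20, n_reps = 10,
                            seed = 5)
  expect_lt(abs(cur$accuracy[2] - full$accuracy), 0.1)

  # pure noise: flat at chance
  gen0 <- function(sequence, position, u) 8
  rms0 <- synthetic_rate_matrices(gen0, n_per_type = 10, n_units = 60,
                                  noise = 2, seed = 23)
  cur0 <- ensemble_size_curve(rms0, "P1", "Odor", sizes = c(5, 60),
                              n_pseudo = 12, n_reps = 10, seed = 6)
  expect_lt(max(abs(cur0$accuracy - 0.5)), 0.15)

  expect_error(ensemble_size_curve(rms0, "P1", "Odor", sizes = c(10, 500)),
               "available units")
})

test_that("position decoding generalizes across sequences when responses match", {
  g <- fixture_group("compressed", n_units = 30, n_rep = 12, seed = 301)
  pd_w <- position_decoding(g$sessions, "within", n_iter = 20,
                            n_per_type = 10, seed = 8)
  pd_a <- position_decoding(g$sessions, "across", n_iter = 20,
                            n_per_type = 10, seed = 8)
  expect_equal(dim(pd_w$confusion), c(4L, 4L))
  expect_equal(unname(rowSums(pd_w$confusion)), rep(1, 4))
  expect_equal(pd_w$chance, 0.25)
  # strong position tuning: well above chance within sequence
  expect_gt(pd_w$accuracy, 0.7)
  # compressed responses transfer across sequences
  expect_gt(pd_a$accuracy, pd_w$accuracy - 0.2)
})
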