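test_that("CP recovers a noiseless rank-1 tensor exactly", {
  fac <- with_seed(1, list(matrix(runif(12, 0.2, 1), 12),
                           matrix(runif(8, 0.2, 1), 8),
                           matrix(runif(10, 0.2, 1), 10)))
  X <- tensor_from_factors(fac)
  m <- cp_fit(X, 1, seed = 2, tol = 1e-12, max_iter = 500)
  expect_lt(m$error, 1e-6)
  cg <- factor_congruence(m, fac)
  expect_true(all(cg >= 0.9999))
  expect_lt(reconstruction_error(m, X), 1e-6)
})

test_that("reconstruction error is monotone even at excessive rank", {
  X <- tensor_from_factors(with_seed(3, list(matrix(runif(8), 4),
                                             matrix(runif(6), 3),
                                             matrix(runif(4), 2))))
  # rank far above the identifiability bound still runs, error only decreases
  m <- expect_silent(cp_fit(X, 8, seed = 1, tol = 1e-10, max_iter = 200))
  expect_true(all(diff(m$error_history) <= 1e-7))
  m2 <- cp_fit(X, 2, seed = 5, tol = 1e-10, max_iter = 300)
  expect_true(all(diff(m2$error_history) <= 1e-7))
})

test_that("planted rank-3 factors are recovered under 5% noise", {
  fac <- with_seed(7, list(matrix(runif(90, 0, 1), 30),
                           matrix(runif(60, 0, 1), 20),
                           matrix(runif(75, 0, 1), 25)))
  X <- tensor_from_factors(fac, lambda = c(3, 2, 1.5), noise = 0.05, seed = 8)
  X[X < 0] <- 0
  ens <- restart_ensemble(X, 3, n_restarts = 20, seed = 9, tol = 1e-8,
                          max_iter = 400)
  best <- ens$models[[ens$best]]
  cg <- factor_congruence(best, fac)
  expect_true(all(cg >= 0.95))
})

test_that("noiseless low-rank tensors are recovered to high congruence", {
  for (R in 2:3) {
    # well-separated factors: near-orthogonal blocks
    fac <- lapply(c(12, 9, 9), function(n) {
      A <- matrix(0.05, n, R)
      for (r in seq_len(R)) A[((r - 1) * 3 + 1):(r * 3), r] <- 1
      A
    })
    X <- tensor_from_factors(fac)
    ens <- restart_ensemble(X, R, n_restarts = 5, seed = R, tol = 1e-12,
                            max_iter = 500)
    cg <- factor_congruence(ens$models[[ens$best]], fac)
    expect_true(all(cg >= 0.999))
  }
})

test_that("reconstruction error has the stated fixed points", {
  m <- random_cp_model(c(4, 3, 2), 2, seed = 1)
  X <- cp_reconstruct(m)
  expect_equal(reconstruction_error(m, X), 0, tolerance = 1e-10)

  zero <- m; zero$lambda <- c(0, 0)
  expect_equal(reconstruction_error(zero, X), 1)

  expect_warning(v <- reconstruction_error(m, array(0, c(4, 3, 2))),
                 "zero tensor")
  expect_true(is.na(v))

  # hand-built 2x2x2 arithmetic oracle
  u <- c(1, 2); v2 <- c(1, 0.5); w <- c(2, 1)
  mm <- structure(list(rank = 1L,
                       factors = list(unit = matrix(u / sqrt(5)),
                                      time = matrix(v2 / sqrt(1.25)),
                                      trial = matrix(w / sqrt(5))),
                       lambda = sqrt(5) * sqrt(1.25) * sqrt(5)),
                  class = "cp_model")
  Xh <- outer(outer(u, v2), w)
  Xobs <- Xh + 0.1
  direct <- sqrt(sum((Xobs - Xh)^2)) / sqrt(sum(Xobs^2))
  expect_equal(reconstruction_error(mm, Xobs), direct, tolerance = 1e-12)
})

test_that("optimal assignment matches exhaustive search", {
  for (n in c(2, 4, 5)) {
    cost <- with_seed(n, matrix(rnorm(n * n), n))
    got <- stategen:::assignment_min(cost)
    perms <- combinat_perms(seq_len(n))
    vals <- vapply(perms, function(p) sum(cost[cbind(seq_len(n), p)]), 0)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), min(vals),
                 tolerance = 1e-12)
  }
})

test_that("similarity score is a permutation/scale-invariant match measure", {
  m <- random_cp_model(c(15, 10, 12), 5, seed = 21)
  expect_equal(similarity_score(m, m), 1, tolerance = 1e-12)

  # permuted and rescaled copy still scores 1
  perm <- c(3, 1, 5, 2, 4)
  m2 <- m
  m2$factors <- lapply(m$factors, function(A) A[, perm])
  m2$lambda <- (m$lambda * c(2, 0.5, 1, 3, 1.2))[perm]
  expect_equal(similarity_score(m, m2), 1, tolerance = 1e-12)

  # independent random (signed) factor models: far from similar --
  # nonnegative random factors all live in the positive orthant and are
  # never dissimilar by a cosine measure, so the null uses signed factors
  sims <- vapply(1:5, function(i)
    similarity_score(random_cp_model(c(40, 30, 35), 10, seed = 100 + i,
                                     nonneg = FALSE),
                     random_cp_model(c(40, 30, 35), 10, seed = 200 + i,
                                     nonneg = FALSE)), 0)
  expect_true(all(sims < 0.3))

  expect_error(similarity_score(m, random_cp_model(c(15, 10, 12), 4, 1)),
               "rank")
})

test_that("similarity score agrees with the exhaustive-permutation reference", {
  for (i in 1:6) {
    a <- random_cp_model(c(9, 7, 8), 5, seed = 300 + i)
    b <- random_cp_model(c(9, 7, 8), 5, seed = 400 + i)
    expect_equal(similarity_score(a, b), similarity_bruteforce(a, b),
                 tolerance = 1e-6)
  }
  # and on a realistic pair: two fits of the same small tensor
  X <- tensor_from_factors(with_seed(5, list(matrix(runif(60), 12),
                                             matrix(runif(40), 8),
                                             matrix(runif(50), 10))),
                           noise = 0.2, seed = 6)
  X[X < 0] <- 0
  f1 <- cp_fit(X, 5, seed = 1, tol = 1e-9, max_iter = 300)
  f2 <- cp_fit(X, 5, seed = 2, tol = 1e-9, max_iter = 300)
  expect_equal(similarity_score(f1, f2), similarity_bruteforce(f1, f2),
               tolerance = 1e-6)
})

test_that("restart ensembles are seeded, ranked by error, and stable on structure", {
  X <- tensor_from_factors(with_seed(11, list(matrix(runif(60), 12),
                                              matrix(runif(40), 8),
                                              matrix(runif(50), 10))),
                           lambda = c(4, 2.5, 2, 1.5, 1), noise = 0.1,
                           seed = 12)
  X[X < 0] <- 0
  ens <- restart_ensemble(X, 5, n_restarts = 10, seed = 13, tol = 1e-8,
                          max_iter = 400)
  expect_equal(ens$best, which.min(ens$errors))
  expect_equal(ens$similarity[ens$best], 1, tolerance = 1e-9)
  # structured tensor: most restarts highly similar to the best fit
  expect_gt(mean(ens$similarity > 0.8), 0.7)

  one <- restart_ensemble(X, 5, n_restarts = 1, seed = 13)
  expect_equal(one$similarity, 1)

  again <- restart_ensemble(X, 5, n_restarts = 10, seed = 13, tol = 1e-8,
                            max_iter = 400)
  expect_identical(vapply(again$models, `[[`, 0, "error"), ens$errors)
})

test_that("cross-group alignment matches components by temporal factors", {
  a <- random_cp_model(c(10, 72, 16), 6, seed = 31)
  b <- a
  perm <- c(4, 6, 1, 3, 2, 5)
  b$factors <- lapply(a$factors, function(A) A[, perm])
  b$lambda <- a$lambda[perm]
  al <- align_across_groups(a, b)
  expect_equal(al$permutation, order(perm))
  # matched pairs are (near) perfectly congruent
  expect_true(all(al$congruence > 0.999))
  expect_true(all(al$matched))

  # orthogonal temporal factors: congruence ~ 0, flagged unmatched
  c1 <- random_cp_model(c(10, 72, 16), 4, seed = 32)
  c2 <- c1
  Q <- with_seed(33, qr.Q(qr(matrix(rnorm(72 * 8), 72))))
  c1$factors$time <- abs(Q[, 1:4]); c2$factors$time <- abs(Q[, 5:8])
  c1$factors$time <- sweep(c1$factors$time, 2,
                           sqrt(colSums(c1$factors$time^2)), `/`)
  c2$factors$time <- sweep(c2$factors$time, 2,
                           sqrt(colSums(c2$factors$time^2)), `/`)
  al2 <- align_across_groups(c1, c2)
  expect_true(all(al2$congruence < 0.9))
  expect_equal(sort(al2$permutation), 1:4)
})

test_that("component summaries classify temporal and trial structure", {
  K <- 48; bs <- 6
  m <- random_cp_model(c(6, 72, K), 3, seed = 41)
  # component 1: uniform trial loadings + structured (early) temporal
  # profile -> position-general
  v1 <- rep(c(1, 0.7, 0.3, rep(0.05, 6)), each = 8)
  m$factors$time[, 1] <- v1 / sqrt(sum(v1^2))
  m$factors$trial[, 1] <- 1 / sqrt(K)
  # component 2: loads only on rewarded blocks (1, 2, 7, 8)
  w <- rep(0, K); w[c(1:(2 * bs), (6 * bs + 1):K)] <- 1
  m$factors$trial[, 2] <- w / sqrt(sum(w))
  # component 3: temporal mass only in the Choice epoch (bins 41-48)
  v <- rep(0, 72); v[41:48] <- 1
  m$factors$time[, 3] <- v / sqrt(8)
  m$lambda <- c(3, 2, 1)
  cs <- component_summary(m)
  expect_true(cs$position_general[1])

  # a temporally featureless component with uniform loadings is the
  # baseline floor, not a position-general response pattern
  flat <- m
  flat$factors$time[, 1] <- rep(1 / sqrt(72), 72)
  expect_false(component_summary(flat)$position_general[1])
  expect_equal(cs$reward_pref[2], "rewarded")
  expect_false(cs$position_general[2])
  expect_equal(cs$dominant_epoch[3], "Choice")

  expect_error(component_summary(random_cp_model(c(5, 60, 48), 2, 1)),
               "72")
})
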