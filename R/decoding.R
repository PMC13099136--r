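## Pseudoensemble decoding: linear SVM with leave-one-out cross-validation
## and label-shuffled permutation nulls.

#' Generate pseudoensembles from an epoch rate matrix
#'
#' A pseudoensemble independently permutes, for every unit, the order of
#' that unit's trials within each trial type, destroying across-unit trial
#' correlations while leaving each unit's per-type rate marginals exactly
#' unchanged. The stream of pseudoensembles is deterministic given the
#' seed.
#'
#' @param rate_matrix An `"epoch_rate_matrix"` (rows blocked by trial
#'   type with equal counts).
#' @param n_pseudo Number of pseudoensembles.
#' @param seed Integer seed.
#' @return List of `n_pseudo` rate matrices, each with attribute
#'   `"labels"` (unchanged row labels).
#' @export
assemble_pseudoensembles <- function(rate_matrix, n_pseudo, seed = 1) {
  lb <- rate_matrix$labels
  counts <- table(lb$trial_type)
  if (length(unique(counts)) != 1L)
    sg_stop("pseudoensembles require equal per-type trial counts")
  x <- rate_matrix$rates
  lapply(seq_len(n_pseudo), function(i)
    with_seed(derive_seed(seed, "pseudo", i), {
      out <- x
      for (b in unique(lb$trial_type)) {
        rows <- which(lb$trial_type == b)
        for (u in seq_len(ncol(x)))
          out[rows, u] <- x[sample(rows), u]
      }
      attr(out, "labels") <- lb
      out
    }))
}

#' Fit a linear maximum-margin decoder
#'
#' Linear support vector machine (hinge loss, regularization constant
#' `cost`), with features standardized by the training data's mean and SD
#' only. Multiclass problems use one-vs-rest with the largest decision
#' value winning; ties break toward the lowest class index.
#'
#' @param x Training matrix (rows = trials, columns = features).
#' @param y Training labels (>= 2 classes present).
#' @param cost SVM regularization constant (default 1).
#' @return Object of class `"linear_decoder"`.
#' @export
linear_decoder_fit <- function(x, y, cost = 1) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) sg_stop("training labels contain a single class")
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  xs <- scale(x, center = mu, scale = sdev)
  models <- lapply(classes, function(k) {
    yk <- factor(ifelse(y == k, "in", "out"), levels = c("in", "out"))
    e1071::svm(xs, yk, kernel = "linear", cost = cost, scale = FALSE)
  })
  structure(list(classes = classes, models = models, mu = mu, sdev = sdev,
                 cost = cost),
            class = "linear_decoder")
}

#' Predict labels with a linear decoder
#' @param decoder A `"linear_decoder"`.
#' @param x Matrix of rows to classify.
#' @return Character vector of predicted labels.
#' @export
linear_decoder_predict <- function(decoder, x) {
  x <- matrix(x, ncol = length(decoder$mu))
  xs <- scale(x, center = decoder$mu, scale = decoder$sdev)
  dv <- vapply(seq_along(decoder$classes), function(k) {
    pr <- stats::predict(decoder$models[[k]], xs, decision.values = TRUE)
    d <- drop(attr(pr, "decision.values"))
    # orient so that larger means "in" regardless of factor-level order
    if (grepl("^out", colnames(attr(pr, "decision.values"))[1])) -d else d
  }, numeric(nrow(xs)))
  dv <- matrix(dv, nrow = nrow(xs))
  decoder$classes[apply(dv, 1, which.max)]   # which.max: lowest index on ties
}

#' Leave-one-out cross-validated decoding accuracy
#'
#' Each repetition holds out one randomly chosen trial per class, trains
#' the linear decoder on the remaining trials, and scores the held-out
#' set; the reported accuracy is the mean over repetitions.
#'
#' @param x Rate matrix (trials x features).
#' @param y Class labels per row.
#' @param n_reps Number of leave-one-out repetitions (default 200).
#' @param seed Integer seed.
#' @param cost SVM regularization constant.
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
loo_accuracy <- function(x, y, n_reps = 200, seed = 1, cost = 1) {
  y <- as.character(y)
  classes <- unique(y)
  idx_by_class <- lapply(classes, function(k) which(y == k))
  hold <- with_seed(derive_seed(seed, "loo"),
                    vapply(seq_len(n_reps), function(i)
                      vapply(idx_by_class, function(ix)
                        ix[sample.int(length(ix), 1L)], 0L),
                      integer(length(classes))))
  hold <- matrix(hold, nrow = length(classes))
  acc <- vapply(seq_len(n_reps), function(i) {
    test <- hold[, i]
    dec <- linear_decoder_fit(x[-test, , drop = FALSE], y[-test], cost = cost)
    mean(linear_decoder_predict(dec, x[test, , drop = FALSE]) == y[test])
  }, 0)
  mean(acc)
}

#' Label-shuffled null distribution for a decoding analysis
#'
#' Permutes the class labels and reruns the identical leave-one-out
#' pipeline `n_shuffles` times; the 95% confidence interval is the
#' 2.5/97.5 percentile band of the null accuracies.
#'
#' @param x Rate matrix (trials x features).
#' @param y Class labels.
#' @param n_shuffles Number of label permutations.
#' @param seed Integer seed.
#' @param n_reps,cost Passed to [loo_accuracy()].
#' @return List: `dist` (null accuracies), `mean`, `ci` (length 2).
#' @export
shuffled_null <- function(x, y, n_shuffles = 100, seed = 1, n_reps = 200,
                          cost = 1) {
  if (n_shuffles < 20L)
    warning("fewer than 20 shuffles: the 95% CI is degenerate")
  dist <- vapply(seq_len(n_shuffles), function(s) {
    yp <- with_seed(derive_seed(seed, "nullperm", s), sample(y))
    loo_accuracy(x, yp, n_reps = n_reps,
                 seed = derive_seed(seed, "nullloo", s), cost = cost)
  }, 0)
  list(dist = dist, mean = mean(dist),
       ci = unname(stats::quantile(dist, c(0.025, 0.975))))
}

subsample_units <- function(x, ensemble_size, seed) {
  if (is.null(ensemble_size) || ensemble_size >= ncol(x)) return(x)
  keep <- with_seed(seed, sample.int(ncol(x), ensemble_size))
  x[, keep, drop = FALSE]
}

#' S1-vs-S2 decoding at one position and epoch
#'
#' Binary decoding of sequence identity from pseudoensemble activity,
#' restricted to the two trial types at the given position; chance is 0.5.
#' Accuracy is averaged over `n_pseudo` pseudoensembles (units subsampled
#' to `ensemble_size` per pseudoensemble) and compared with a
#' label-shuffled null run through the identical pipeline.
#'
#' @param rate_matrices Output of [build_rate_matrices()].
#' @param position `"P1"`..`"P4"`.
#' @param epoch One of the nine epoch labels.
#' @param ensemble_size Units per pseudoensemble (`NULL` = all); must not
#'   exceed the available units.
#' @param n_pseudo Pseudoensembles for the observed accuracy.
#' @param n_shuffles Label permutations for the null.
#' @param n_reps Leave-one-out repetitions per decode.
#' @param seed Integer seed.
#' @param cost SVM regularization constant.
#' @return Object of class `"decoding_result"`: `accuracy`, `per_pseudo`,
#'   `null` (`mean`, `ci`, `dist`), `chance`, `above_null`, annotations.
#' @export
s1_vs_s2_decoding <- function(rate_matrices, position, epoch,
                              ensemble_size = NULL, n_pseudo = 100,
                              n_shuffles = 100, n_reps = 50, seed = 1,
                              cost = 1) {
  rm <- rate_matrices[[epoch]]
  if (is.null(rm)) sg_stop("unknown epoch ", epoch)
  if (!is.null(ensemble_size) && ensemble_size > ncol(rm$rates))
    sg_stop("ensemble_size exceeds the ", ncol(rm$rates), " available units")
  rows <- rm$labels$position == position
  sub <- structure(list(rates = rm$rates[rows, , drop = FALSE],
                        labels = rm$labels[rows, ]),
                   class = "epoch_rate_matrix")
  y <- sub$labels$sequence
  pe <- assemble_pseudoensembles(sub, n_pseudo, derive_seed(seed, "obs"))
  per_pseudo <- vapply(seq_along(pe), function(i) {
    x <- subsample_units(pe[[i]], ensemble_size,
                         derive_seed(seed, "units", i))
    loo_accuracy(x, y, n_reps = n_reps,
                 seed = derive_seed(seed, "obs_loo", i), cost = cost)
  }, 0)
  null_pe <- assemble_pseudoensembles(sub, n_shuffles,
                                      derive_seed(seed, "nullpe"))
  null_dist <- vapply(seq_along(null_pe), function(s) {
    x <- subsample_units(null_pe[[s]], ensemble_size,
                         derive_seed(seed, "nullunits", s))
    yp <- with_seed(derive_seed(seed, "nullperm", s), sample(y))
    loo_accuracy(x, yp, n_reps = n_reps,
                 seed = derive_seed(seed, "null_loo", s), cost = cost)
  }, 0)
  ci <- unname(stats::quantile(null_dist, c(0.025, 0.975)))
  structure(list(accuracy = mean(per_pseudo), per_pseudo = per_pseudo,
                 null = list(mean = mean(null_dist), ci = ci,
                             dist = null_dist),
                 chance = 0.5, above_null = mean(per_pseudo) > ci[2],
                 position = position, epoch = epoch,
                 ensemble_size = ensemble_size %||% ncol(rm$rates),
                 seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", x$epoch, " @ ", x$position,
      ": accuracy ", sprintf("%.3f", x$accuracy),
      " (chance ", x$chance, ", null 95% CI ",
      sprintf("%.3f-%.3f", x$null$ci[1], x$null$ci[2]), ")",
      if (x$above_null) " *", "\n", sep = "")
  invisible(x)
}

#' Within- and across-sequence position decoding
#'
#' Four-class position decoding from 9-epoch rate-vector features
#' (chance 0.25). In each iteration, `n_per_type` correct trials per
#' position are sampled per sequence, giving a trials x epochs feature
#' matrix per unit (120 x 9 at the default), concatenated over units. One
#' trial per position is held out from S1; the classifier is trained on
#' the remaining S1 trials and tested on the held-out S1 trials (`within`
#' mode) and on the index-matched S2 trials (`across` mode).
#'
#' @param sessions List of `"session_record"`s.
#' @param mode `"within"` or `"across"`.
#' @param n_iter Number of sample/hold-out iterations (default 1000).
#' @param n_per_type Trials sampled per position and sequence.
#' @param ensemble_size Units used (`NULL` = all), sampled once per
#'   iteration across the pooled units.
#' @param seed Integer seed.
#' @param cost SVM regularization constant.
#' @param params Binning parameters.
#' @param rates Optional precomputed [epoch_rates()] list.
#' @return List of class `"position_decoding_result"`: `accuracy`,
#'   `confusion` (4 x 4, rows = actual position, rows sum to 1), `mode`,
#'   `chance`, `n_iter`.
#' @export
position_decoding <- function(sessions, mode = c("within", "across"),
                              n_iter = 1000, n_per_type = 30,
                              ensemble_size = NULL, seed = 1, cost = 1,
                              params = binning_params(), rates = NULL) {
  mode <- match.arg(mode)
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  if (is.null(rates)) rates <- lapply(sessions, epoch_rates, params = params)
  n_units <- sum(vapply(rates, function(r) dim(r$mean_rates)[1], 0L))
  confusion <- matrix(0, 4, 4, dimnames = list(POSITIONS, POSITIONS))
  hits <- 0; total <- 0
  for (it in seq_len(n_iter)) {
    fs <- lapply(SEQUENCES, function(sq) {
      mats <- lapply(seq_along(sessions), function(s)
        position_feature_matrix(sessions[[s]], sq, n_per_type,
                                seed = derive_seed(seed, "iter", it),
                                params = params, rates = rates[[s]])$features)
      do.call(cbind, mats)
    })
    names(fs) <- SEQUENCES
    if (!is.null(ensemble_size)) {
      ucols <- with_seed(derive_seed(seed, "units", it),
                         sample.int(n_units, ensemble_size))
      cols <- as.vector(outer(1:9, (ucols - 1L) * 9L, `+`))
      fs <- lapply(fs, function(m) m[, cols, drop = FALSE])
    }
    pos_lab <- rep(POSITIONS, each = n_per_type)
    hold <- with_seed(derive_seed(seed, "hold", it),
                      vapply(0:3, function(p)
                        p * n_per_type + sample.int(n_per_type, 1L), 0))
    dec <- linear_decoder_fit(fs$S1[-hold, , drop = FALSE], pos_lab[-hold],
                              cost = cost)
    test_x <- if (mode == "within") fs$S1[hold, , drop = FALSE]
              else fs$S2[hold, , drop = FALSE]
    pred <- linear_decoder_predict(dec, test_x)
    actual <- pos_lab[hold]
    hits <- hits + sum(pred == actual); total <- total + length(pred)
    for (i in seq_along(pred))
      confusion[actual[i], pred[i]] <- confusion[actual[i], pred[i]] + 1
  }
  confusion <- confusion / rowSums(confusion)
  structure(list(accuracy = hits / total, confusion = confusion,
                 mode = mode, chance = 0.25, n_iter = n_iter, seed = seed),
            class = "position_decoding_result")
}

#' @export
print.position_decoding_result <- function(x, ...) {
  cat("<position_decoding_result> ", x$mode, "-sequence accuracy ",
      sprintf("%.3f", x$accuracy), " (chance ", x$chance, ", ",
      x$n_iter, " iterations)\n", sep = "")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Decoding accuracy as a function of ensemble size
#'
#' Repeats S1-vs-S2 decoding at one position/epoch for a grid of ensemble
#' sizes; informative signals yield non-decreasing accuracy in
#' expectation.
#'
#' @param rate_matrices Output of [build_rate_matrices()].
#' @param position,epoch Cell to decode.
#' @param sizes Integer vector of ensemble sizes (default
#'   `c(10, 20, 50, 100, 200, 500)`, truncated to the available units).
#' @param n_pseudo,n_reps,seed,cost As in [s1_vs_s2_decoding()].
#' @return Data.frame: `size`, `accuracy`, plus attribute `"per_pseudo"`
#'   (matrix of per-pseudoensemble accuracies, paired across sizes).
#' @export
ensemble_size_curve <- function(rate_matrices, position, epoch,
                                sizes = c(10, 20, 50, 100, 200, 500),
                                n_pseudo = 50, n_reps = 50, seed = 1,
                                cost = 1) {
  avail <- ncol(rate_matrices[[1]]$rates)
  if (max(sizes) > avail)
    sg_stop("max(sizes) exceeds the ", avail, " available units")
  rm <- rate_matrices[[epoch]]
  rows <- rm$labels$position == position
  sub <- structure(list(rates = rm$rates[rows, , drop = FALSE],
                        labels = rm$labels[rows, ]),
                   class = "epoch_rate_matrix")
  y <- sub$labels$sequence
  pe <- assemble_pseudoensembles(sub, n_pseudo, derive_seed(seed, "sizes"))
  per <- matrix(0, n_pseudo, length(sizes),
                dimnames = list(NULL, paste0("n", sizes)))
  for (j in seq_along(sizes)) {
    for (i in seq_len(n_pseudo)) {
      x <- subsample_units(pe[[i]], sizes[j],
                           derive_seed(seed, "size_units", j, i))
      per[i, j] <- loo_accuracy(x, y, n_reps = n_reps,
                                seed = derive_seed(seed, "size_loo", j, i),
                                cost = cost)
    }
  }
  out <- data.frame(size = sizes, accuracy = colMeans(per))
  attr(out, "per_pseudo") <- per
  out
}
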