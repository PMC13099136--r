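## Mutual information between CP trial-factor loadings and trial
## type / time, estimated by the plug-in (histogram) estimator in bits.

bin_equal_width <- function(x, n_bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
}

bin_equal_count <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(x)))
}

plugin_mi_bits <- function(bx, by, miller_madow = FALSE) {
  joint <- table(bx, by)
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  if (miller_madow) {
    # Miller-Madow: the joint entropy is underestimated by ~(K-1)/2N, so
    # the plug-in MI is biased UP by (Kxy - Kx - Ky + 1)/2N nats
    kxy <- sum(joint > 0); kx <- sum(px > 0); ky <- sum(py > 0)
    mi <- mi - (kxy - kx - ky + 1) / (2 * n * log(2))
  }
  max(mi, 0)
}

#' Mutual information between trial-factor loadings and trial type
#'
#' Plug-in MI (base-2 logarithm) from the joint histogram of the
#' equal-width-binned loadings and the 8 trial types. Bounded above by
#' `log2(8) = 3` bits for complete sessions.
#'
#' @param loadings Numeric trial-factor loadings (length K).
#' @param types Trial-type labels (1..8) per trial.
#' @param n_bins Loading bins (default 8).
#' @param miller_madow Apply the Miller--Madow small-sample correction?
#' @return MI in bits (0 for constant loadings).
#' @export
mi_factor_vs_type <- function(loadings, types, n_bins = 8,
                              miller_madow = FALSE) {
  stopifnot(length(loadings) == length(types))
  plugin_mi_bits(bin_equal_width(loadings, n_bins), types, miller_madow)
}

#' Mutual information between trial-factor loadings and time
#'
#' "Time" is the trial index within the session, discretized into
#' `n_bins` equal-count bins; loadings are equal-width binned. Plug-in
#' estimator, base-2 logarithm.
#'
#' @param loadings Numeric trial-factor loadings (length K).
#' @param indices Trial indices (default `seq_along(loadings)`).
#' @param n_bins Bins for both variables (default 8).
#' @param miller_madow Apply the Miller--Madow correction?
#' @return MI in bits.
#' @export
mi_factor_vs_time <- function(loadings, indices = seq_along(loadings),
                              n_bins = 8, miller_madow = FALSE) {
  stopifnot(length(loadings) == length(indices))
  plugin_mi_bits(bin_equal_width(loadings, n_bins),
                 bin_equal_count(indices, n_bins), miller_madow)
}

#' Per-component MI profile over a restart ensemble
#'
#' Aligns every restart model to the ensemble's best-fit model by optimal
#' congruence matching, drops restarts whose mean matched congruence falls
#' below 0.5, and reports the mean and SEM over the retained restarts of
#' each component's MI with trial type and with time.
#'
#' @param ensemble A `"cp_restart_ensemble"`.
#' @param types Trial-type labels per trial-mode index (1..8).
#' @param indices Chronological trial index of each trial-mode slice
#'   (e.g. the `chron_index` column of a trial tensor's labels; the trial
#'   mode is blocked by type, so the slice index is not session time);
#'   defaults to the slice index.
#' @param n_bins Histogram bins (default 8).
#' @param miller_madow Apply the Miller--Madow correction?
#' @return Object of class `"mi_result"`: data.frame with one row per
#'   component of the best-fit model (`mi_type`, `mi_type_sem`, `mi_time`,
#'   `mi_time_sem`, `n_restarts`), plus attributes `n_bins` and `dropped`.
#' @export
mi_profile <- function(ensemble, types, indices = NULL, n_bins = 8,
                       miller_madow = FALSE) {
  if (!length(ensemble$models)) sg_stop("empty restart ensemble")
  best <- ensemble$models[[ensemble$best]]
  K <- nrow(best$factors$trial)
  stopifnot(length(types) == K)
  if (is.null(indices)) indices <- seq_len(K)
  R <- best$rank
  mt <- mtime <- matrix(NA_real_, length(ensemble$models), R)
  dropped <- integer(0)
  for (m in seq_along(ensemble$models)) {
    mod <- ensemble$models[[m]]
    C <- congruence_matrix(best, mod)
    perm <- assignment_min(-C)
    if (mean(C[cbind(seq_len(R), perm)]) < 0.5) {
      dropped <- c(dropped, m)
      next
    }
    for (r in seq_len(R)) {
      ld <- mod$factors$trial[, perm[r]]
      mt[m, r] <- mi_factor_vs_type(ld, types, n_bins, miller_madow)
      mtime[m, r] <- mi_factor_vs_time(ld, indices, n_bins, miller_madow)
    }
  }
  if (length(dropped))
    message("mi_profile: dropped ", length(dropped),
            " restart(s) with mean congruence < 0.5")
  keep <- setdiff(seq_along(ensemble$models), dropped)
  if (!length(keep)) sg_stop("no restart aligned to the best-fit model")
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  out <- data.frame(
    component = seq_len(R),
    mi_type = colMeans(mt[keep, , drop = FALSE]),
    mi_type_sem = apply(mt[keep, , drop = FALSE], 2, sem),
    mi_time = colMeans(mtime[keep, , drop = FALSE]),
    mi_time_sem = apply(mtime[keep, , drop = FALSE], 2, sem),
    n_restarts = length(keep))
  attr(out, "n_bins") <- n_bins
  attr(out, "dropped") <- dropped
  class(out) <- c("mi_result", "data.frame")
  out
}
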