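#' Per-unit sequence selectivity at one position and epoch
#'
#' Two-sided test of whether a unit's post-event rates differ between S1
#' and S2 trials at the same position. The default is the Wilcoxon rank-sum
#' test (robust to the skewed rate distributions typical of cortical
#' units); a Welch t-test is available as an alternative.
#'
#' @param s1_rates,s2_rates Per-trial epoch mean rates (Hz).
#' @param alpha Significance level for the selectivity flag.
#' @param method `"wilcox"` (default) or `"ttest"`.
#' @return List: `selective` (logical), `statistic`, `p`.
#' @export
sequence_selectivity <- function(s1_rates, s2_rates, alpha = 0.05,
                                 method = c("wilcox", "ttest")) {
  method <- match.arg(method)
  if (length(s1_rates) < 5L || length(s2_rates) < 5L)
    sg_stop("need >= 5 trials per sequence")
  if (method == "wilcox") {
    ht <- suppressWarnings(stats::wilcox.test(s1_rates, s2_rates,
                                              exact = FALSE))
  } else {
    ht <- stats::t.test(s1_rates, s2_rates)
  }
  p <- ht$p.value
  if (is.na(p)) p <- 1   # e.g. all rates identical
  list(selective = p < alpha, statistic = unname(ht$statistic), p = p)
}

#' Per-unit selectivity table over all epochs and positions
#'
#' Applies [sequence_selectivity()] to every (unit, epoch, position) cell
#' of a set of per-epoch rate matrices.
#'
#' @param rate_matrices Output of [build_rate_matrices()].
#' @param alpha Significance level.
#' @param method Test passed to [sequence_selectivity()].
#' @return Data.frame with one row per (unit, epoch, position):
#'   `session`, `unit_id`, `group_label`, `epoch`, `position`,
#'   `statistic`, `p`, `selective`.
#' @export
selectivity_table <- function(rate_matrices, alpha = 0.05,
                              method = "wilcox") {
  info <- rate_matrices[[1]]$unit_info
  out <- vector("list", 9L * 4L)
  k <- 0L
  for (e in EPOCHS) {
    rm <- rate_matrices[[e]]
    for (p in POSITIONS) {
      i1 <- rm$labels$position == p & rm$labels$sequence == "S1"
      i2 <- rm$labels$position == p & rm$labels$sequence == "S2"
      res <- lapply(seq_len(ncol(rm$rates)), function(u)
        sequence_selectivity(rm$rates[i1, u], rm$rates[i2, u],
                             alpha = alpha, method = method))
      k <- k + 1L
      out[[k]] <- data.frame(
        session = info$session, unit_id = info$unit_id,
        group_label = info$group_label, epoch = e, position = p,
        statistic = vapply(res, `[[`, 0, "statistic"),
        p = vapply(res, `[[`, 0, "p"),
        selective = vapply(res, `[[`, TRUE, "selective"))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  res
}

#' Fraction of selective units per (epoch, position) cell
#'
#' @param table Output of [selectivity_table()].
#' @return Data.frame over the 36 cells: `epoch`, `position`,
#'   `n_selective`, `n_tested`, `fraction`.
#' @export
selectivity_fraction_curve <- function(table) {
  agg <- stats::aggregate(selective ~ epoch + position, data = table,
                          FUN = function(x) c(sum(x), length(x)))
  out <- data.frame(epoch = agg$epoch, position = agg$position,
                    n_selective = agg$selective[, 1],
                    n_tested = agg$selective[, 2])
  out$fraction <- out$n_selective / out$n_tested
  out$epoch <- factor(out$epoch, levels = EPOCHS)
  out[order(out$position, out$epoch), ]
}

#' Chi-squared comparison of selective fractions between two groups
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2 x 2
#' table (selective / not x group), per cell.
#'
#' @param sel_a,n_a Selective count and total tested in group A (vectors
#'   over cells, or scalars).
#' @param sel_b,n_b Same for group B.
#' @return Data.frame with `chisq` and `p` per cell; cells with a zero
#'   margin get statistic 0 and p = 1 (with a message).
#' @export
compare_fractions <- function(sel_a, n_a, sel_b, n_b) {
  m <- max(length(sel_a), length(sel_b))
  sel_a <- rep_len(sel_a, m); n_a <- rep_len(n_a, m)
  sel_b <- rep_len(sel_b, m); n_b <- rep_len(n_b, m)
  chisq <- p <- numeric(m)
  for (i in seq_len(m)) {
    tab <- matrix(c(sel_a[i], n_a[i] - sel_a[i],
                    sel_b[i], n_b[i] - sel_b[i]), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      message("compare_fractions: zero margin in cell ", i,
              "; statistic set to 0")
      chisq[i] <- 0; p[i] <- 1
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chisq[i] <- unname(ht$statistic); p[i] <- ht$p.value
    }
  }
  data.frame(chisq = chisq, p = p)
}

#' Two-way fixed-effects ANOVA for one unit
#'
#' Balanced two-way ANOVA of per-trial rates with sequence and position as
#' factors; partial effect sizes are `SS_effect / (SS_effect + SS_error)`.
#'
#' @param rates Per-trial rates (Hz).
#' @param sequence,position Factors (S1/S2, P1..P4), one value per trial.
#' @return Object of class `"anova_result"`: data.frame with rows
#'   `sequence`, `position`, `sequence:position` and columns `df`, `F`,
#'   `p`, `eta_p2`.
#' @export
two_way_anova_unit <- function(rates, sequence, position) {
  d <- data.frame(rate = rates, sequence = factor(sequence),
                  position = factor(position))
  if (any(table(d$sequence, d$position) < 2L))
    sg_stop("need >= 2 trials per (sequence x position) cell")
  if (stats::var(rates) < 1e-20) {
    res <- data.frame(effect = c("sequence", "position", "sequence:position"),
                      df = c(1L, 3L, 3L), F = 0, p = 1, eta_p2 = 0)
    return(structure(res, class = c("anova_result", "data.frame")))
  }
  fit <- stats::aov(rate ~ sequence * position, data = d)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  sse <- ss[4]
  res <- data.frame(
    effect = c("sequence", "position", "sequence:position"),
    df = tab[["Df"]][1:3],
    F = tab[["F value"]][1:3],
    p = tab[["Pr(>F)"]][1:3],
    eta_p2 = ss[1:3] / (ss[1:3] + sse))
  res$F[is.na(res$F)] <- 0
  res$p[is.na(res$p)] <- 1
  structure(res, class = c("anova_result", "data.frame"))
}

#' Prevalence of sequence x position interactions across units
#'
#' Runs [two_way_anova_unit()] on every unit of a rate-matrix set for one
#' epoch and tabulates how many show a significant interaction.
#'
#' @param rate_matrix One `"epoch_rate_matrix"`.
#' @param alpha Significance level for the interaction flag.
#' @return List: `per_unit` (data.frame of interaction F/p per unit),
#'   `n_significant`, `fraction`.
#' @export
interaction_prevalence <- function(rate_matrix, alpha = 0.05) {
  lb <- rate_matrix$labels
  res <- lapply(seq_len(ncol(rate_matrix$rates)), function(u) {
    a <- two_way_anova_unit(rate_matrix$rates[, u], lb$sequence, lb$position)
    a[a$effect == "sequence:position", c("F", "p")]
  })
  per_unit <- do.call(rbind, res)
  per_unit$unit <- seq_len(nrow(per_unit))
  list(per_unit = per_unit,
       n_significant = sum(per_unit$p < alpha),
       fraction = mean(per_unit$p < alpha))
}

#' Cross-sequence correlation of preferred positions
#'
#' Identifies position-selective units independently on each sequence and
#' at each epoch (one-way ANOVA across the four positions, p < `alpha`);
#' for units selective on both sequences the preferred position is the one
#' with the highest mean rate. Preferences are pooled over epochs and
#' correlated across sequences on their ordinal codes 1..4.
#'
#' @param rate_matrices Output of [build_rate_matrices()].
#' @param alpha Selectivity threshold (default 0.01).
#' @param method Correlation method: `"pearson"` (default) or
#'   `"spearman"`.
#' @return List of class `"preferred_position_pairs"`: `pairs` (data.frame
#'   `unit`, `epoch`, `pref_s1`, `pref_s2`), `r`, `n`; `r` is `NA` when
#'   fewer than 5 pairs are available.
#' @export
preferred_position_analysis <- function(rate_matrices, alpha = 0.01,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pairs <- list()
  for (e in EPOCHS) {
    rm <- rate_matrices[[e]]
    for (u in seq_len(ncol(rm$rates))) {
      pref <- rep(NA_integer_, 2)
      for (s in 1:2) {
        rows <- rm$labels$sequence == SEQUENCES[s]
        rates <- rm$rates[rows, u]
        pos <- factor(rm$labels$position[rows])
        ht <- tryCatch(stats::oneway.test(rates ~ pos, var.equal = TRUE),
                       error = function(e) NULL)
        pv <- if (is.null(ht) || is.na(ht$p.value)) 1 else ht$p.value
        if (pv < alpha)
          pref[s] <- which.max(tapply(rates, pos, mean))
      }
      if (!anyNA(pref))
        pairs[[length(pairs) + 1L]] <-
          data.frame(unit = u, epoch = e, pref_s1 = pref[1], pref_s2 = pref[2])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(unit = integer(), epoch = character(),
               pref_s1 = integer(), pref_s2 = integer())
  r <- if (nrow(pairs) >= 5L)
    stats::cor(pairs$pref_s1, pairs$pref_s2, method = method) else NA_real_
  structure(list(pairs = pairs, r = r, n = nrow(pairs), method = method),
            class = "preferred_position_pairs")
}

#' Fisher r-to-z comparison of two correlation coefficients
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return List: `z`, `p`.
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) sg_stop("need n > 3 in both groups")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    sg_stop("|r| = 1: the r-to-z transform diverges")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
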