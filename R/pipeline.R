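#' Pipeline configuration
#'
#' Bundles every stage parameter with defaults matching the standard
#' protocol where one exists (30 trials per type, rank-10 CP with 100
#' restarts, 8 MI bins, 200 leave-one-out repetitions). The pseudoensemble
#' and shuffle counts default to desk-scale values; the full-scale protocol
#' value (10,000 pseudoensembles) is available by configuration.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param templates Template names to simulate.
#' @param n_units,n_sessions Simulated population size per group.
#' @param n_per_type Correct trials selected per trial type.
#' @param n_pseudo,n_shuffles,n_reps Decoding repetition counts.
#' @param ensemble_size Units per pseudoensemble (`NULL` = all).
#' @param decode_positions,decode_epochs Cells for S1-vs-S2 decoding.
#' @param position_iter Iterations for within/across position decoding.
#' @param rank,n_restarts,cp_tol,cp_max_iter CP decomposition settings.
#' @param mi_bins Histogram bins for trial-factor MI.
#' @param alpha Selectivity significance level.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1,
                            templates = c("compressed", "differentiated"),
                            n_units = 300, n_sessions = 1,
                            n_per_type = 30,
                            n_pseudo = 100, n_shuffles = 100, n_reps = 200,
                            ensemble_size = NULL,
                            decode_positions = POSITIONS,
                            decode_epochs = EPOCHS,
                            position_iter = 200,
                            rank = 10, n_restarts = 100,
                            cp_tol = 1e-6, cp_max_iter = 500,
                            mi_bins = 8, alpha = 0.05) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage_csv <- function(x, out_dir, name) {
  utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates each configured template group, then runs every analysis
#' stage: per-epoch rate matrices, per-unit selectivity and group
#' chi-squared comparison, S1-vs-S2 decoding with label-shuffled nulls,
#' within/across-sequence position decoding, CP decomposition with restart
#' diagnostics, component summaries and cross-group alignment,
#' trial-factor MI, and behavioral metrics. Every output is written as CSV
#' alongside the fully resolved configuration (`config.json`); identical
#' configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf <- file.path(out_dir, "run.log")
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  results <- list(config = config)
  groups <- list()
  for (tpl in config$templates) {
    note("simulating ", tpl, " group (", config$n_units, " units x ",
         config$n_sessions, " session(s))")
    template <- population_template(tpl, n_units = config$n_units)
    groups[[tpl]] <- simulate_group(template, config$n_sessions,
                                    seed = derive_seed(config$seed, "sim", tpl))
  }
  results$groups <- groups

  sel_tables <- list()
  for (tpl in names(groups)) {
    note("rate matrices + selectivity: ", tpl)
    g <- groups[[tpl]]
    rates <- lapply(g$sessions, epoch_rates)
    rm <- build_rate_matrices(g$sessions, config$n_per_type,
                              seed = derive_seed(config$seed, "select", tpl),
                              rates = rates)
    tab <- selectivity_table(rm, alpha = config$alpha)
    frac <- selectivity_fraction_curve(tab)
    write_stage_csv(tab, out_dir, paste0("selectivity_units_", tpl))
    write_stage_csv(frac, out_dir, paste0("selectivity_fractions_", tpl))
    sel_tables[[tpl]] <- list(matrices = rm, rates = rates,
                              table = tab, fractions = frac)
  }
  results$selectivity <- lapply(sel_tables, function(x)
    x[c("table", "fractions")])

  if (length(groups) == 2L) {
    a <- sel_tables[[1]]$fractions; b <- sel_tables[[2]]$fractions
    cmp <- cbind(a[, c("epoch", "position")],
                 compare_fractions(a$n_selective, a$n_tested,
                                   b$n_selective, b$n_tested))
    write_stage_csv(cmp, out_dir, "selectivity_group_chisq")
    results$group_chisq <- cmp
  }

  decode_rows <- list()
  for (tpl in names(groups)) {
    for (p in config$decode_positions) for (e in config$decode_epochs) {
      dr <- s1_vs_s2_decoding(sel_tables[[tpl]]$matrices, p, e,
                              ensemble_size = config$ensemble_size,
                              n_pseudo = config$n_pseudo,
                              n_shuffles = config$n_shuffles,
                              n_reps = config$n_reps,
                              seed = derive_seed(config$seed, "s1s2",
                                                 tpl, p, e))
      decode_rows[[length(decode_rows) + 1L]] <- data.frame(
        group = tpl, position = p, epoch = e, accuracy = dr$accuracy,
        null_mean = dr$null$mean, null_lo = dr$null$ci[1],
        null_hi = dr$null$ci[2], above_null = dr$above_null)
    }
    note("S1-vs-S2 decoding done: ", tpl)
  }
  results$s1s2 <- do.call(rbind, decode_rows)
  write_stage_csv(results$s1s2, out_dir, "decoding_s1_vs_s2")

  pos_rows <- list()
  for (tpl in names(groups)) {
    for (mode in c("within", "across")) {
      pd <- position_decoding(groups[[tpl]]$sessions, mode,
                              n_iter = config$position_iter,
                              n_per_type = config$n_per_type,
                              seed = derive_seed(config$seed, "pos",
                                                 tpl, mode),
                              rates = sel_tables[[tpl]]$rates)
      pos_rows[[length(pos_rows) + 1L]] <- data.frame(
        group = tpl, mode = mode, accuracy = pd$accuracy)
      write_stage_csv(as.data.frame(pd$confusion), out_dir,
                      paste0("confusion_", tpl, "_", mode))
    }
    note("position decoding done: ", tpl)
  }
  results$position <- do.call(rbind, pos_rows)
  write_stage_csv(results$position, out_dir, "decoding_position")

  tca <- list()
  for (tpl in names(groups)) {
    note("CP decomposition: ", tpl, " (rank ", config$rank, ", ",
         config$n_restarts, " restarts)")
    tensor <- build_trial_tensor(groups[[tpl]]$sessions,
                                 rates = sel_tables[[tpl]]$rates)
    ens <- restart_ensemble(tensor, config$rank, config$n_restarts,
                            seed = derive_seed(config$seed, "cp", tpl),
                            tol = config$cp_tol,
                            max_iter = config$cp_max_iter)
    best <- ens$models[[ens$best]]
    summ <- component_summary(best)
    mi <- mi_profile(ens, tensor$trial_labels$trial_type,
                     tensor$trial_labels$chron_index,
                     n_bins = config$mi_bins)
    for (mode in c("unit", "time", "trial"))
      write_stage_csv(as.data.frame(best$factors[[mode]]), out_dir,
                      paste0("cp_", tpl, "_", mode, "_factors"))
    write_stage_csv(data.frame(restart = seq_along(ens$errors),
                               error = ens$errors,
                               similarity = ens$similarity),
                    out_dir, paste0("cp_", tpl, "_stability"))
    write_stage_csv(summ, out_dir, paste0("cp_", tpl, "_components"))
    write_stage_csv(as.data.frame(mi), out_dir, paste0("mi_", tpl))
    tca[[tpl]] <- list(tensor = tensor, ensemble = ens, summary = summ,
                       mi = mi)
  }
  results$tca <- tca

  if (length(tca) == 2L) {
    al <- align_across_groups(tca[[1]]$ensemble$models[[tca[[1]]$ensemble$best]],
                              tca[[2]]$ensemble$models[[tca[[2]]$ensemble$best]])
    write_stage_csv(data.frame(component = seq_along(al$permutation),
                               matched_component = al$permutation,
                               congruence = al$congruence,
                               matched = al$matched),
                    out_dir, "cp_group_alignment")
    results$alignment <- al
  }

  beh <- do.call(rbind, lapply(names(groups), function(tpl) {
    tb <- behavior_table(groups[[tpl]]$sessions)
    tb$group <- tpl
    tb
  }))
  write_stage_csv(beh, out_dir, "behavior")
  diffs <- do.call(rbind, lapply(names(groups), function(tpl) {
    d <- sequence_difference_scores(beh[beh$group == tpl, ])
    d$group <- tpl
    d
  }))
  write_stage_csv(diffs, out_dir, "behavior_difference_scores")
  results$behavior <- list(table = beh, diffs = diffs)
  note("pipeline complete")
  invisible(results)
}

#' Render a summary report of pipeline outputs
#'
#' Reads the CSV outputs of [run_pipeline()] and draws the headline
#' panels (selectivity curves, decoding accuracy with null bands,
#' confusion matrices, CP stability and MI summaries) into a single PDF.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param file Output PDF path (default `report.pdf` inside `out_dir`).
#' @return The PDF path, invisibly.
#' @export
make_report <- function(out_dir, file = file.path(out_dir, "report.pdf")) {
  read_maybe <- function(name) {
    f <- file.path(out_dir, paste0(name, ".csv"))
    if (file.exists(f)) utils::read.csv(f) else NULL
  }
  cfg <- jsonlite::read_json(file.path(out_dir, "config.json"),
                             simplifyVector = TRUE)
  grDevices::pdf(file, width = 9, height = 6)
  on.exit(grDevices::dev.off())
  cols <- c(compressed = "black", differentiated = "red")

  fracs <- lapply(cfg$templates, function(tpl)
    read_maybe(paste0("selectivity_fractions_", tpl)))
  names(fracs) <- cfg$templates
  if (!all(vapply(fracs, is.null, TRUE))) {
    graphics::par(mfrow = c(1, 4), mar = c(6, 4, 3, 1))
    for (p in POSITIONS) {
      graphics::plot(NULL, xlim = c(1, 9), ylim = c(0, 1), xaxt = "n",
                     xlab = "", ylab = "fraction selective", main = p)
      graphics::axis(1, at = 1:9, labels = EPOCHS, las = 2, cex.axis = 0.7)
      graphics::abline(h = cfg$alpha, lty = 3)
      for (tpl in names(fracs)) {
        d <- fracs[[tpl]]
        if (is.null(d)) next
        d <- d[d$position == p, ]
        d <- d[match(EPOCHS, d$epoch), ]
        graphics::lines(1:9, d$fraction, col = cols[[tpl]], type = "b",
                        pch = 16)
      }
    }
  }

  s1s2 <- read_maybe("decoding_s1_vs_s2")
  if (!is.null(s1s2)) {
    graphics::par(mfrow = c(1, 4), mar = c(6, 4, 3, 1))
    for (p in unique(s1s2$position)) {
      d0 <- s1s2[s1s2$position == p, ]
      graphics::plot(NULL, xlim = c(1, length(unique(d0$epoch))),
                     ylim = c(0.3, 1), xaxt = "n", xlab = "",
                     ylab = "S1 vs S2 accuracy", main = p)
      eps <- unique(d0$epoch)
      graphics::axis(1, at = seq_along(eps), labels = eps, las = 2,
                     cex.axis = 0.7)
      graphics::abline(h = 0.5, lty = 3)
      for (tpl in unique(d0$group)) {
        d <- d0[d0$group == tpl, ]
        x <- seq_along(eps)
        graphics::polygon(c(x, rev(x)), c(d$null_lo, rev(d$null_hi)),
                          col = grDevices::adjustcolor(cols[[tpl]], 0.15),
                          border = NA)
        graphics::lines(x, d$accuracy, col = cols[[tpl]], type = "b",
                        pch = 16)
      }
    }
  }

  for (tpl in cfg$templates) for (mode in c("within", "across")) {
    cm <- read_maybe(paste0("confusion_", tpl, "_", mode))
    if (is.null(cm)) next
    graphics::par(mfrow = c(1, 1), mar = c(4, 4, 3, 1))
    graphics::image(1:4, 1:4, t(as.matrix(cm))[, 4:1],
                    col = grDevices::hcl.colors(25, "viridis"),
                    axes = FALSE, xlab = "predicted", ylab = "actual",
                    main = paste0(tpl, ": ", mode, "-sequence"))
    graphics::axis(1, 1:4, POSITIONS); graphics::axis(2, 4:1, POSITIONS)
  }

  for (tpl in cfg$templates) {
    st <- read_maybe(paste0("cp_", tpl, "_stability"))
    mi <- read_maybe(paste0("mi_", tpl))
    if (!is.null(st)) {
      graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
      graphics::plot(st$error, st$similarity, xlab = "reconstruction error",
                     ylab = "similarity to best fit", ylim = c(0, 1),
                     main = paste0(tpl, ": CP restarts"), pch = 16,
                     col = cols[[tpl]])
      graphics::abline(h = 0.8, lty = 3)
      if (!is.null(mi)) {
        graphics::plot(mi$component, mi$mi_type, type = "b", pch = 16,
                       ylim = range(0, mi$mi_type, mi$mi_time),
                       xlab = "component", ylab = "MI (bits)",
                       main = paste0(tpl, ": trial-factor MI"))
        graphics::lines(mi$component, mi$mi_time, type = "b", pch = 1,
                        lty = 2)
        graphics::legend("topright", c("vs type", "vs time"),
                         pch = c(16, 1), lty = c(1, 2), bty = "n")
      }
    }
  }
  invisible(file)
}
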