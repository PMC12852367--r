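#' Pipeline configuration
#'
#' Bundles every stage's parameters with their protocol defaults: 50 Hz
#' notch, 200 Hz analysis rate, 60-s post-block windows, SO detection
#' band 0.16--1.25 Hz with the 65th-percentile individualized threshold,
#' 10--20 Hz Morlet TFR with TFCE permutation statistics, SO-spindle
#' coupling bands 0.5--1.25 / 12--15 Hz, and the 1--45 Hz aperiodic fit.
#'
#' @param n_subjects cohort size
#' @param effects planted condition effects (see [cohort_plan()])
#' @param seed master seed controlling every random draw
#' @param synth baseline [synth_config()]
#' @param protocol a [stim_protocol()]
#' @param so [so_params()]
#' @param tfce [tfce_params()]
#' @param notch_base notch base frequency in Hz (NULL disables)
#' @param target_fs analysis sampling rate in Hz
#' @param so_band,spindle_band band-power ranges in Hz
#' @param slope_range aperiodic fit range in Hz
#' @param do_tfce run the TFCE permutation contrasts
#' @param conditions condition labels (first is the reference/sham)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(n_subjects = 22, effects = list(), seed = 1L,
                            synth = synth_config(),
                            protocol = stim_protocol(),
                            so = so_params(), tfce = tfce_params(),
                            notch_base = 50, target_fs = 200,
                            so_band = c(0.5, 1), spindle_band = c(12, 15),
                            slope_range = c(1, 45), do_tfce = TRUE,
                            conditions = c("sham", "anodal", "cathodal")) {
  structure(list(n_subjects = n_subjects, effects = effects,
                 seed = as.integer(seed), synth = synth,
                 protocol = protocol, so = so, tfce = tfce,
                 notch_base = notch_base, target_fs = target_fs,
                 so_band = so_band, spindle_band = spindle_band,
                 slope_range = slope_range, do_tfce = do_tfce,
                 conditions = conditions),
            class = "pipeline_config")
}

#' Analyze one recording end to end
#'
#' Runs the single-session feature extraction: channel selection, optional
#' notch, resampling to the analysis rate, interval extraction, per-window
#' Welch band power and aperiodic slope, SO detection with the
#' individualized threshold, SO-locked TFR subject mean, and event-locked
#' SO-spindle coupling.
#'
#' @param rec a [recording()]
#' @param config a [pipeline_config()]
#' @return list of per-session features
#' @export
analyze_recording <- function(rec, config = pipeline_config()) {
  if (rec$fs > config$target_fs) rec <- resample(rec, config$target_fs)
  ch <- select_channel(rec)
  sig <- ch$signal
  if (!is.null(config$notch_base) && config$notch_base < rec$fs / 2) {
    sig <- notch_filter(sig, base = config$notch_base, fs = rec$fs)
  }
  ivs <- extract_intervals(rec)
  post <- ivs[ivs$kind == "post_block", , drop = FALSE]
  base <- ivs[ivs$kind == "pre_stim_baseline" & !ivs$clipped, ,
              drop = FALSE]
  bp_rows <- list(); slope_rows <- list()
  for (i in seq_len(nrow(post))) {
    seg <- cut_segment(sig, rec$fs, post$start[i], post$stop[i])
    ps <- welch_psd(seg, rec$fs)
    for (bn in c("so", "spindle")) {
      bd <- if (bn == "so") config$so_band else config$spindle_band
      bp <- band_power(ps, bd)
      bp_rows[[length(bp_rows) + 1L]] <- data.frame(
        interval = post$block_index[i], band = bn,
        absolute = bp$absolute, relative = bp$relative)
    }
    sf <- fit_spectral_slope(ps, config$slope_range)
    slope_rows[[length(slope_rows) + 1L]] <- data.frame(
      interval = post$block_index[i], kind = "post_block",
      slope = sf$slope, exponent_x = sf$exponent_x,
      r_squared = sf$r_squared)
  }
  for (i in seq_len(nrow(base))) {
    seg <- cut_segment(sig, rec$fs, base$start[i], base$stop[i])
    sf <- fit_spectral_slope(welch_psd(seg, rec$fs), config$slope_range)
    slope_rows[[length(slope_rows) + 1L]] <- data.frame(
      interval = 0L, kind = "pre_stim_baseline", slope = sf$slope,
      exponent_x = sf$exponent_x, r_squared = sf$r_squared)
  }
  det <- detect_so_in_recording(rec, config$so, intervals = ivs)
  blocks <- rec$annotations[rec$annotations$label == "STIM_BLOCK", ]
  avoid <- cbind(blocks$onset, blocks$onset + blocks$duration)
  epochs <- extract_event_epochs(sig, det$events, rec$fs, avoid = avoid)
  tfr_mean <- NULL
  pac <- NULL
  if (length(epochs) > 0) {
    tfrs <- lapply(epochs, function(ep) {
      zscore_baseline(morlet_tfr(ep, rec$fs))
    })
    tfr_mean <- subject_mean_tfr(tfrs)
    pac <- event_locked_pac(epochs, rec$fs,
                            so_band = c(0.5, 1.25),
                            spindle_band = config$spindle_band,
                            subject = rec$meta$subject,
                            condition = rec$meta$condition)
  }
  list(subject = rec$meta$subject, condition = rec$meta$condition,
       channel = ch$channel,
       morphology = summarize_morphology(det$events),
       events = det$events, threshold = det$threshold,
       band_power = if (length(bp_rows)) do.call(rbind, bp_rows) else NULL,
       slopes = if (length(slope_rows)) do.call(rbind, slope_rows)
                else NULL,
       tfr_mean = tfr_mean, coupling = pac,
       n_epochs = length(epochs))
}

# subject x condition mean of one outcome column -> long table
outcome_table <- function(df, value_col) {
  out <- stats::aggregate(df[[value_col]],
                          by = list(subject = df$subject,
                                    condition = df$condition), mean)
  names(out)[3] <- "value"
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates (lazily, one session at a time) the synthetic cohort defined
#' by the configuration, extracts per-session features, and runs the
#' group-level statistics: repeated-measures ANOVAs with
#' Greenhouse-Geisser correction and Holm-adjusted planned contrasts for
#' each outcome, Watson-Williams comparisons of the mean coupling phase,
#' the condition x MEQ repeated-measures ANCOVA, the mixed
#' condition x chronotype ANOVA, the slope-vs-spindle-power regression,
#' the MEQ correlation with the anodal spindle change, and (optionally)
#' TFCE permutation maps for each active condition against the reference.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional directory: tables are written as CSV plus a
#'   JSON manifest
#' @return list with `tables` (data frames), `stats`, `tfr`, `manifest`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  plan <- cohort_plan(config$n_subjects, config$effects, config$seed,
                      config$synth, config$protocol, config$conditions)
  cells <- list()
  skipped <- character(0)
  for (s in plan$subjects$subject) {
    for (cnd in config$conditions) {
      key <- paste(s, cnd, sep = ".")
      res <- tryCatch({
        cell <- realize_cohort_cell(plan, s, cnd)
        analyze_recording(cell$recording, config)
      }, error = function(e) {
        message("skipping ", key, ": ", conditionMessage(e))
        conditionMessage(e)
      })
      if (is.character(res)) skipped[key] <- res else cells[[key]] <- res
    }
  }
  grab <- function(fn) do.call(rbind, lapply(cells, fn))
  so_tbl <- grab(function(x) cbind(data.frame(subject = x$subject,
                                              condition = x$condition),
                                   x$morphology))
  bp_tbl <- grab(function(x) if (is.null(x$band_power)) NULL else
    cbind(data.frame(subject = x$subject, condition = x$condition),
          x$band_power))
  slope_tbl <- grab(function(x) if (is.null(x$slopes)) NULL else
    cbind(data.frame(subject = x$subject, condition = x$condition),
          x$slopes))
  coup_tbl <- grab(function(x) {
    if (is.null(x$coupling) || length(x$coupling$phases) == 0) return(NULL)
    cs <- circular_summary(x$coupling)
    data.frame(subject = x$subject, condition = x$condition,
               mean_angle = cs$mean_angle, R = cs$R,
               n_events = cs$n_events)
  })
  phase_tbl <- grab(function(x) {
    if (is.null(x$coupling) || length(x$coupling$phases) == 0) return(NULL)
    data.frame(subject = x$subject, condition = x$condition,
               event = seq_along(x$coupling$phases),
               phase = x$coupling$phases)
  })
  subjects <- plan$subjects
  rownames(so_tbl) <- NULL
  # outcome tables: one value per subject x condition
  outcomes <- list(
    so_count = stats::setNames(so_tbl[, c("subject", "condition", "count")],
                               c("subject", "condition", "value")),
    downstate_mag = stats::setNames(
      so_tbl[, c("subject", "condition", "downstate_mag")],
      c("subject", "condition", "value")),
    neg_halfwave_dur = stats::setNames(
      so_tbl[, c("subject", "condition", "neg_halfwave_dur")],
      c("subject", "condition", "value")),
    pos_halfwave_dur = stats::setNames(
      so_tbl[, c("subject", "condition", "pos_halfwave_dur")],
      c("subject", "condition", "value")))
  if (!is.null(bp_tbl)) {
    sp <- bp_tbl[bp_tbl$band == "spindle", ]
    so_p <- bp_tbl[bp_tbl$band == "so", ]
    outcomes$spindle_power <- outcome_table(sp, "relative")
    outcomes$so_power <- outcome_table(so_p, "relative")
  }
  if (!is.null(slope_tbl)) {
    post_slopes <- slope_tbl[slope_tbl$kind == "post_block", ]
    outcomes$spectral_slope <- outcome_table(post_slopes, "slope")
  }
  if (!is.null(coup_tbl)) {
    outcomes$coupling_strength <- stats::setNames(
      coup_tbl[, c("subject", "condition", "R")],
      c("subject", "condition", "value"))
  }
  active <- setdiff(config$conditions, config$conditions[1])
  pairs <- lapply(active, function(a) c(a, config$conditions[1]))
  stats_out <- list()
  for (nm in names(outcomes)) {
    tab <- outcomes[[nm]]
    res <- tryCatch({
      om <- rm_anova(tab)
      ct <- planned_contrasts_holm(tab, pairs,
                                   omnibus_significant = om$p < 0.05)
      list(omnibus = om, contrasts = ct)
    }, error = function(e) list(error = conditionMessage(e)))
    stats_out[[nm]] <- res
  }
  # circular comparison of mean coupling phases
  if (!is.null(coup_tbl)) {
    groups <- split(coup_tbl$mean_angle, coup_tbl$condition)
    groups <- groups[config$conditions[config$conditions %in%
                                         names(groups)]]
    stats_out$coupling_phase <- lapply(pairs, function(pr) {
      res <- tryCatch(
        watson_williams(list(groups[[pr[1]]], groups[[pr[2]]])),
        error = function(e) list(error = conditionMessage(e)))
      res$pair <- paste(pr, collapse = "-")
      if (!is.null(groups[[pr[1]]]) && !is.null(groups[[pr[2]]])) {
        res$mean_diff <- circ_diff_deg(circ_mean_deg(groups[[pr[1]]]),
                                       circ_mean_deg(groups[[pr[2]]]))
      }
      res
    })
  }
  # chronotype moderation on spindle power
  if (!is.null(outcomes$spindle_power)) {
    tab <- merge(outcomes$spindle_power, subjects, by = "subject")
    stats_out$meq_moderation <- tryCatch(
      rm_ancova_moderation(tab), error = function(e)
        list(error = conditionMessage(e)))
    stats_out$chronotype_mixed <- tryCatch(
      mixed_anova_chronotype(tab), error = function(e)
        list(error = conditionMessage(e)))
    # MEQ vs anodal-sham spindle change
    if ("anodal" %in% tab$condition) {
      w <- wide_conditions(outcomes$spindle_power)
      if (all(c("anodal", "sham") %in% colnames(w))) {
        change <- (w[, "anodal"] - w[, "sham"]) / w[, "sham"] * 100
        meq <- subjects$meq[match(rownames(w), subjects$subject)]
        stats_out$meq_vs_spindle_change <- tryCatch(
          pearson_regression(meq, change), error = function(e)
            list(error = conditionMessage(e)))
      }
    }
  }
  # slope vs spindle power regression across subject x condition cells
  if (!is.null(outcomes$spectral_slope) &&
      !is.null(outcomes$spindle_power)) {
    mg <- merge(outcomes$spectral_slope, outcomes$spindle_power,
                by = c("subject", "condition"),
                suffixes = c("_slope", "_spindle"))
    stats_out$slope_vs_spindle <- tryCatch(
      slope_vs_outcome_regression(mg$value_slope, mg$value_spindle),
      error = function(e) list(error = conditionMessage(e)))
  }
  # TFCE contrasts on subject-mean TFR maps
  tfr_out <- list()
  if (config$do_tfce) {
    for (pr in pairs) {
      maps_a <- lapply(plan$subjects$subject, function(s)
        cells[[paste(s, pr[1], sep = ".")]]$tfr_mean)
      maps_b <- lapply(plan$subjects$subject, function(s)
        cells[[paste(s, pr[2], sep = ".")]]$tfr_mean)
      ok <- !vapply(maps_a, is.null, logical(1)) &
        !vapply(maps_b, is.null, logical(1))
      if (sum(ok) >= 2) {
        tm <- paired_t_map(maps_a[ok], maps_b[ok])
        tfr_out[[paste(pr, collapse = "-")]] <- suppressWarnings(
          tfce_permutation(tm, config$tfce, seed = config$seed + 7L))
      }
    }
  }
  manifest <- list(seed = config$seed, n_subjects = config$n_subjects,
                   conditions = config$conditions,
                   effects = plan$effects,
                   synth = unclass(config$synth),
                   protocol = unclass(config$protocol),
                   so = unclass(config$so),
                   tfce = unclass(config$tfce),
                   bands = list(so = config$so_band,
                                spindle = config$spindle_band,
                                slope = config$slope_range))
  manifest$skipped_cells <- as.list(skipped)
  out <- list(tables = list(subjects = subjects, so_morphology = so_tbl,
                            band_power = bp_tbl, slopes = slope_tbl,
                            coupling = coup_tbl, phases = phase_tbl),
              outcomes = outcomes, stats = stats_out, tfr = tfr_out,
              manifest = manifest, skipped = skipped)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results$tables)) {
    tab <- results$tables[[nm]]
    if (is.null(tab)) next
    rownames(tab) <- NULL
    utils::write.csv(tab, file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(results$tfr)) {
    msk <- results$tfr[[nm]]$significant_mask
    cells <- which(msk, arr.ind = TRUE)
    df <- data.frame(
      time = results$tfr[[nm]]$times[cells[, 1]],
      freq = results$tfr[[nm]]$freqs[cells[, 2]])
    utils::write.csv(df, file.path(out_dir,
                                   paste0("tfce_mask_", nm, ".csv")),
                     row.names = FALSE)
  }
  writeLines(report(results), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' Human-readable pipeline report
#'
#' @param results a [run_pipeline()] result bundle
#' @return character vector of report lines
#' @export
report <- function(results) {
  ln <- c("Sleep-oscillation pipeline report",
          "=================================", "")
  for (nm in names(results$stats)) {
    st <- results$stats[[nm]]
    if (nm %in% c("coupling_phase")) next
    if (!is.null(st$error)) {
      ln <- c(ln, sprintf("%s: not computed (%s)", nm, st$error))
      next
    }
    if (!is.null(st$omnibus)) {
      om <- st$omnibus
      ln <- c(ln, sprintf(
        "%s: F(%.2f, %.2f) = %.3f, p = %s (GG eps = %.3f, pes = %.3f)",
        nm, om$df1_gg, om$df2_gg, om$F, fmt_p(om$p), om$gg_epsilon,
        om$partial_eta_sq))
      ct <- st$contrasts
      for (i in seq_len(nrow(ct))) {
        ln <- c(ln, sprintf(
          "  contrast %s (Holm family of %d): p-adj = %s, d = %.3f",
          ct$pair[i], nrow(ct), fmt_p(ct$p_adj[i]), ct$cohens_d[i]))
      }
    } else if (nm == "meq_moderation" && !is.null(st$F)) {
      ln <- c(ln, sprintf(
        "condition x MEQ interaction: F(%d, %d) = %.3f, p(GG) = %s",
        st$df1, st$df2, st$F, fmt_p(st$p)))
    } else if (nm == "chronotype_mixed" && !is.null(st$interaction)) {
      it <- st$interaction
      ln <- c(ln, sprintf(
        "condition x chronotype interaction: F(%d, %d) = %.3f, p(GG) = %s",
        it$df1, it$df2, it$F, fmt_p(it$p)))
    } else if (nm == "meq_vs_spindle_change" && !is.null(st$r)) {
      ln <- c(ln, sprintf(
        "MEQ vs anodal spindle change: r = %.3f, p = %s, R^2 = %.3f",
        st$r, fmt_p(st$p), st$r_squared))
    } else if (nm == "slope_vs_spindle" && !is.null(st$B)) {
      ln <- c(ln, sprintf(
        "slope -> spindle power: B = %.4g, beta = %.3f, p = %s, R^2 = %.3f",
        st$B, st$beta, fmt_p(st$p), st$r_squared))
    }
  }
  cp <- results$stats$coupling_phase
  if (is.null(cp)) {
    ln <- c(ln, "", "coupling: no events")
  } else {
    ln <- c(ln, "", "Coupling phase (Watson-Williams):")
    for (res in cp) {
      if (!is.null(res$error)) {
        ln <- c(ln, sprintf("  %s: not computed (%s)", res$pair, res$error))
      } else {
        ln <- c(ln, sprintf(
          "  %s: F(%d, %d) = %.3f, p = %s, mean diff = %.2f deg",
          res$pair, res$df1, res$df2, res$F, fmt_p(res$p), res$mean_diff))
      }
    }
  }
  for (nm in names(results$tfr)) {
    n_sig <- sum(results$tfr[[nm]]$significant_mask)
    ln <- c(ln, sprintf("TFCE %s: %d significant (time, freq) cells%s",
                        nm, n_sig,
                        if (results$tfr[[nm]]$exact) " [exact]" else ""))
  }
  ln
}
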