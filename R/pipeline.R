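#' Run the EEG (passive listening) arm on a synthetic cohort
#'
#' For each EEG participant: generate (or accept) beat-locked epochs,
#' band-pass filter (1-49 Hz, zero phase), re-reference to the average,
#' Morlet-decompose (6-48 Hz linear grid, fixed 500 ms window) the three
#' left-motor channels, compute ITC, average the maps over C5/C3/C1 and over
#' the alpha band (8-14 Hz), and extract the trough/peak/slope features.
#' Group level: mean/SD of each feature, paired t test of trough vs peak
#' ITC, and the positive-slope fraction.
#'
#' @param cohort A [gen_cohort()] object with an EEG arm.
#' @param fs Sampling rate for generation/analysis.
#' @param step_ms TFR output time step.
#' @param verbose Print per-participant progress.
#' @return List with `features` (per-participant data frame), `group`
#'   (means/SDs), `trough_vs_peak` (paired t row or NULL if n < 2),
#'   `positive_slope_fraction`, `n`.
#' @export
run_eeg_study <- function(cohort, fs = 1000, step_ms = 10, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$eeg_truth) || nrow(cohort$eeg_truth) == 0L) {
    stop("cohort has no EEG participants")
  }
  n <- nrow(cohort$eeg_truth)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ep <- cohort_eeg(cohort, i, fs = fs)
    ep$data <- bandpass_epochs(ep)$data
    ep <- rereference_average(ep)
    tf <- morlet_transform(ep, channels = motor_channels(), step_ms = step_ms)
    alpha <- channel_average(band_average(itc(tf), c(8, 14)))
    rows[[i]] <- cbind(participant = cohort$eeg_truth$participant[i],
                       itc_features(alpha))
    if (verbose) {
      message(sprintf("EEG %d/%d: trough %.0f ms (%.3f), peak %.0f ms (%.3f)",
                      i, n, rows[[i]]$trough_time_ms, rows[[i]]$trough_itc,
                      rows[[i]]$peak_time_ms, rows[[i]]$peak_itc))
    }
  }
  feats <- do.call(rbind, rows)
  num <- c("trough_time_ms", "trough_itc", "peak_time_ms", "peak_itc", "slope", "rise")
  group <- data.frame(field = num,
                      mean = vapply(num, function(f) mean(feats[[f]]), numeric(1)),
                      sd = vapply(num, function(f) stats::sd(feats[[f]]), numeric(1)),
                      row.names = NULL)
  tvp <- if (n >= 2L) paired_t(feats$trough_itc, feats$peak_itc) else NULL
  list(features = feats, group = group, trough_vs_peak = tvp,
       positive_slope_fraction = positive_slope_fraction(feats), n = n)
}

# Zero-phase band-pass of every channel/trial in an epochs object.
bandpass_epochs <- function(epochs, low = 1, high = 49) {
  d <- dim(epochs$data)
  for (k in seq_len(d[3])) {
    epochs$data[, , k] <- bandpass(epochs$data[, , k], epochs$fs, low, high)
  }
  epochs
}

#' Run the MEP arm on a synthetic cohort
#'
#' For each MEP participant and condition: generate TMS-locked EMG trials,
#' run the filter chain ([mep_filter_chain()]), and collect per-participant
#' kept-trial mean peak-to-peak amplitudes. Group level: per-condition
#' means/SDs/95% CIs, paired comparisons of seTMS against both control
#' conditions with percent-change summaries, and trial-rejection summaries.
#'
#' @param cohort A [gen_cohort()] object with an MEP arm.
#' @param fs EMG sampling rate.
#' @param verbose Print per-participant progress.
#' @return List with `per_participant` (data frame of condition means),
#'   `condition_summary`, `setms_vs_standard`, `setms_vs_auditory`
#'   ([compare_conditions()] results; NULL if n < 2), `rejection_summary`.
#' @export
run_mep_study <- function(cohort, fs = 5000, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$emg_truth) || nrow(cohort$emg_truth) == 0L) {
    stop("cohort has no MEP participants")
  }
  n <- nrow(cohort$emg_truth)
  conds <- c("setms", "standard", "auditory_control")
  pp <- data.frame(participant = cohort$emg_truth$participant)
  for (cd in conds) pp[[cd]] <- NA_real_
  rej <- numeric(0)
  for (i in seq_len(n)) {
    sets <- cohort_emg(cohort, i, fs = fs)
    for (cd in conds) {
      res <- mep_filter_chain(sets[[cd]])
      pp[[cd]][i] <- res$mean_p2p
      rej <- c(rej, res$fraction_rejected)
    }
    if (verbose) {
      message(sprintf("MEP %d/%d: %s", i, n,
                      paste(sprintf("%s %.2f", conds, unlist(pp[i, conds])), collapse = ", ")))
    }
  }
  summ <- do.call(rbind, lapply(conds, function(cd) {
    v <- pp[[cd]]
    se <- stats::sd(v) / sqrt(n)
    tc <- if (n >= 2L) stats::qt(0.975, n - 1L) else NA_real_
    data.frame(condition = cd, n = n, mean_p2p = mean(v), sd_p2p = stats::sd(v),
               ci95_low = mean(v) - tc * se, ci95_high = mean(v) + tc * se)
  }))
  cmp_std <- if (n >= 2L) compare_conditions(pp$setms, pp$standard) else NULL
  cmp_aud <- if (n >= 2L) compare_conditions(pp$setms, pp$auditory_control) else NULL
  list(per_participant = pp, condition_summary = summ,
       setms_vs_standard = cmp_std, setms_vs_auditory = cmp_aud,
       rejection_summary = data.frame(mean_fraction_rejected = mean(rej),
                                      sd_fraction_rejected = stats::sd(rej)),
       n = n)
}

#' Run the default replication study on a synthetic cohort
#'
#' Builds the default cohort (27 EEG + 19 MEP participants, group
#' calibration from [cohort_spec()] defaults) seeded by `seed`, runs both
#' study arms, and assembles a machine-readable report of the headline
#' quantities. Fully deterministic given `seed`.
#'
#' @param seed Master seed.
#' @param n_eeg,n_mep Cohort sizes (defaults are the study's).
#' @param eeg_fs,emg_fs Sampling rates.
#' @param verbose Print progress.
#' @return A `setms_report` list with `eeg`, `mep`, and `provenance`
#'   sections.
#' @export
run_default_replication <- function(seed = 0L, n_eeg = 27, n_mep = 19,
                                    eeg_fs = 1000, emg_fs = 5000,
                                    verbose = FALSE) {
  spec <- cohort_spec(n_eeg = n_eeg, n_mep = n_mep, master_seed = seed)
  cohort <- gen_cohort(spec)
  eeg <- if (n_eeg > 0) run_eeg_study(cohort, fs = eeg_fs, verbose = verbose) else NULL
  mep <- if (n_mep > 0) run_mep_study(cohort, fs = emg_fs, verbose = verbose) else NULL
  structure(
    list(eeg = eeg, mep = mep,
         provenance = list(seed = seed, n_eeg = n_eeg, n_mep = n_mep,
                           eeg_fs = eeg_fs, emg_fs = emg_fs,
                           package_version = as.character(utils::packageVersion("setms")),
                           parameters = list(
                             filter_band_hz = c(1, 49), wavelet_grid_hz = c(6, 48, 1),
                             wavelet_window_ms = 500, baseline_ms = c(-500, -200),
                             alpha_band_hz = c(8, 14), beta_band_hz = c(20, 26),
                             trough_window_ms = c(-222, -99), peak_window_ms = c(0, 101),
                             emg_baseline_ms = c(-20, -5), rms_window_ms = c(-200, 13),
                             rms_omit_ms = c(-5, 5), rms_sd_mult = 2.5,
                             biphasic_window_ms = c(15, 40), biphasic_k = 3,
                             outlier_sd_mult = 5, p2p_window_ms = c(18, 50),
                             pulse_offset_ms = -200, min_isi_s = 3))),
    class = "setms_report"
  )
}

#' Serialize a replication report to JSON
#'
#' @param report A `setms_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

#' @export
print.setms_report <- function(x, ...) {
  cat("<setms_report>\n")
  if (!is.null(x$eeg)) {
    g <- x$eeg$group
    gm <- function(f) g$mean[g$field == f]
    cat(sprintf("  EEG (n=%d): trough %.2f ms (ITC %.3f), peak %.2f ms (ITC %.3f), positive slopes %.1f%%\n",
                x$eeg$n, gm("trough_time_ms"), gm("trough_itc"),
                gm("peak_time_ms"), gm("peak_itc"),
                100 * x$eeg$positive_slope_fraction))
    if (!is.null(x$eeg$trough_vs_peak)) {
      cat(sprintf("       trough vs peak ITC: t(%d) = %.2f, p = %.3g\n",
                  x$eeg$trough_vs_peak$df, x$eeg$trough_vs_peak$t_stat,
                  x$eeg$trough_vs_peak$p_value))
    }
  }
  if (!is.null(x$mep)) {
    s <- x$mep$condition_summary
    cat(sprintf("  MEP (n=%d): %s\n", x$mep$n,
                paste(sprintf("%s %.2f mV", s$condition, s$mean_p2p), collapse = ", ")))
    if (!is.null(x$mep$setms_vs_standard)) {
      cat(sprintf("       seTMS vs standard: t(%d) = %.2f, p = %.3g; mean %%change %.1f (median %.1f)\n",
                  x$mep$setms_vs_standard$t$df, x$mep$setms_vs_standard$t$t_stat,
                  x$mep$setms_vs_standard$t$p_value,
                  x$mep$setms_vs_standard$mean_percent_change,
                  x$mep$setms_vs_standard$median_percent_change))
    }
  }
  invisible(x)
}
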