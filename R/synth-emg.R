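#' Participant-level synthetic EMG/MEP parameters
#'
#' Ground truth for one synthetic participant's TMS-locked EMG trials:
#' per-condition mean peak-to-peak MEP amplitude, trial-to-trial amplitude
#' dispersion (lognormal coefficient of variation), MEP latency, trial
#' counts, and the fractions of seeded artifact / outlier / absent-response
#' trials.
#'
#' @param mean_amp_mV Named numeric: mean peak-to-peak amplitude (mV) per
#'   condition, names `setms`, `standard`, `auditory_control`; all > 0.
#' @param amp_cv Coefficient of variation of the per-trial lognormal
#'   amplitudes. MEP amplitudes are strongly right-skewed; 0.5 gives a
#'   standard error of roughly 0.15 mV for a 100-trial mean at the 3 mV scale.
#' @param mep_latency_ms MEP onset latency in ms, within [15, 40] so clean
#'   trials pass the biphasic window check. Latencies above ~30 ms push the
#'   second lobe outside the 40 ms biphasic window.
#' @param n_trials Trials per condition.
#' @param artifact_fraction Fraction of trials seeded with tonic pre-pulse
#'   muscle activity (rejected by the RMS rule).
#' @param outlier_fraction Fraction of trials seeded with amplitudes far
#'   above the clean mean (rejected by the 5 SD rule).
#' @param absent_fraction Fraction of trials with no MEP (rejected by the
#'   biphasic rule).
#' @param noise_sd_mV Background EMG noise SD (relaxed muscle).
#' @param tonic_factor Tonic artifact amplitude as a multiple of the
#'   background RMS.
#' @param outlier_factor Outlier amplitude as a multiple of the participant's
#'   clean condition mean (6 places them beyond mean + 5 SD at `amp_cv` 0.5).
#' @param seed Integer RNG seed.
#' @return A `participant_emg_params` object.
#' @export
emg_params <- function(mean_amp_mV = c(setms = 3.08, standard = 2.44, auditory_control = 2.38),
                       amp_cv = 0.5, mep_latency_ms = 23, n_trials = 125,
                       artifact_fraction = 0.05, outlier_fraction = 0.01,
                       absent_fraction = 0, noise_sd_mV = 0.006,
                       tonic_factor = 10, outlier_factor = 6, seed = 1L) {
  if (any(mean_amp_mV <= 0)) stop("mean amplitudes must be positive")
  if (mep_latency_ms < 15 || mep_latency_ms > 40) {
    stop("mep_latency_ms must lie in [15, 40]")
  }
  fr <- c(artifact_fraction, outlier_fraction, absent_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("artifact/outlier/absent fractions must be in [0, 1] and sum to <= 1")
  }
  stopifnot(all(c("setms", "standard", "auditory_control") %in% names(mean_amp_mV)))
  structure(as.list(environment()), class = "participant_emg_params")
}

#' Biphasic MEP template
#'
#' Difference of two Gaussians: a positive lobe followed by a negative lobe,
#' 5 ms SD each, centers 10 ms apart, the first centered 5 ms after the
#' onset latency. Scaled so the template's peak-to-peak amplitude is exactly
#' `amp_mV`.
#'
#' @param time_ms Pulse-relative sample times in ms.
#' @param latency_ms Onset latency in ms.
#' @param amp_mV Peak-to-peak amplitude in mV.
#' @param lobe_sd_ms Gaussian lobe SD in ms.
#' @param lobe_gap_ms Center-to-center lobe separation in ms.
#' @return Numeric vector of the template sampled at `time_ms`.
#' @export
mep_template <- function(time_ms, latency_ms = 23, amp_mV = 1,
                         lobe_sd_ms = 5, lobe_gap_ms = 10) {
  c1 <- latency_ms + 5
  c2 <- c1 + lobe_gap_ms
  shape <- exp(-(time_ms - c1)^2 / (2 * lobe_sd_ms^2)) -
           exp(-(time_ms - c2)^2 / (2 * lobe_sd_ms^2))
  p2p <- max(shape) - min(shape)
  shape * (amp_mV / p2p)
}

#' Generate synthetic TMS-locked EMG trials for one condition
#'
#' Clean trials contain the biphasic MEP template on low-amplitude background
#' EMG noise, with per-trial peak-to-peak amplitudes drawn lognormally around
#' the condition mean. Seeded artifact trials carry tonic activity at
#' `tonic_factor` times the background RMS across the pre-pulse window (so
#' the RMS rejection rule flags them); seeded outlier trials carry amplitudes
#' at `outlier_factor` times the clean mean (flagged by the 5 SD rule);
#' absent-response trials carry noise only (flagged by the biphasic rule).
#' Ground-truth per-trial labels and amplitudes are recorded in the
#' `ground_truth` attribute, which downstream analysis code must not read.
#'
#' @param params An [emg_params()] object.
#' @param condition Condition to generate (`setms`, `standard`,
#'   `auditory_control`).
#' @param plan Optional [schedule_pulses()] plan; if given, its condition
#'   must match and its pulse count caps the trial count.
#' @param fs Sampling rate in Hz.
#' @param window_ms Trial window around the pulse; must cover [-200, 60] ms.
#' @param participant_id Identifier stored in the trial set.
#' @return An `emg_trials` object: list with `data` (trials x samples, mV),
#'   `fs`, `time_ms`, `condition`, `participant_id`.
#' @export
gen_emg_trials <- function(params, condition = c("setms", "standard", "auditory_control"),
                           plan = NULL, fs = 5000, window_ms = c(-200, 60),
                           participant_id = "P01") {
  stopifnot(inherits(params, "participant_emg_params"))
  condition <- match.arg(condition)
  if (window_ms[1] > -200 || window_ms[2] < 60) {
    stop("trial window must cover [-200, 60] ms")
  }
  n <- params$n_trials
  if (!is.null(plan)) {
    if (plan$condition != condition) stop("plan condition does not match")
    n <- min(n, length(plan$pulse_times_s))
  }
  time_ms <- seq(round(window_ms[1] * fs / 1000), round(window_ms[2] * fs / 1000)) / fs * 1000
  ns <- length(time_ms)
  mean_amp <- unname(params$mean_amp_mV[[condition]])
  n_art <- round(params$artifact_fraction * n)
  n_out <- round(params$outlier_fraction * n)
  n_abs <- round(params$absent_fraction * n)
  cls <- rep("clean", n)
  special <- seq_len(n_art + n_out + n_abs)
  cls[special] <- rep(c("artifact", "outlier", "absent"), c(n_art, n_out, n_abs))
  sdlog <- sqrt(log(1 + params$amp_cv^2))
  meanlog <- log(mean_amp) - sdlog^2 / 2
  dat <- matrix(0, n, ns)
  amp <- numeric(n)
  with_preserved_seed(params$seed, {
    cls <- sample(cls)                                # seeded positions
    amp <- stats::rlnorm(n, meanlog, sdlog)
    amp[cls == "outlier"] <- params$outlier_factor * mean_amp
    amp[cls == "absent"] <- 0
    for (k in seq_len(n)) {
      tr <- stats::rnorm(ns, 0, params$noise_sd_mV)
      if (cls[k] != "absent") {
        tr <- tr + mep_template(time_ms, params$mep_latency_ms, amp[k])
      }
      if (cls[k] == "artifact") {
        pre <- time_ms <= 13
        tr[pre] <- tr[pre] + stats::rnorm(sum(pre), 0,
                                          params$tonic_factor * params$noise_sd_mV)
      }
      dat[k, ] <- tr
    }
  })
  out <- structure(
    list(data = dat, fs = fs, time_ms = time_ms, condition = condition,
         participant_id = participant_id),
    class = "emg_trials"
  )
  attr(out, "ground_truth") <- data.frame(
    trial = seq_len(n), class = cls, true_amp_mV = amp,
    stringsAsFactors = FALSE
  )
  out
}

#' @export
print.emg_trials <- function(x, ...) {
  cat(sprintf("<emg_trials> %s %s: %d trials x %d samples @ %g Hz, window [%g, %g] ms\n",
              x$participant_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
              min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Write EMG trials to a delimited matrix with JSON header and truth TSV
#'
#' @param trials An `emg_trials` object.
#' @param path Output TSV path (rows = trials, columns = samples). The JSON
#'   header goes to `paste0(path, ".json")` and, when present, the
#'   ground-truth table to `paste0(path, ".truth.tsv")`.
#' @return `path`, invisibly.
#' @export
write_emg_delim <- function(trials, path) {
  utils::write.table(format(trials$data, digits = 10, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  hdr <- list(fs = trials$fs, window_ms = range(trials$time_ms),
              n_samples = ncol(trials$data), n_trials = nrow(trials$data),
              pulse_sample_index = which.min(abs(trials$time_ms)),
              condition = trials$condition, participant_id = trials$participant_id)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  gt <- attr(trials, "ground_truth")
  if (!is.null(gt)) {
    utils::write.table(gt, paste0(path, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read EMG trials written by [write_emg_delim()]
#' @param path TSV path.
#' @return An `emg_trials` object (without ground truth).
#' @export
read_emg_delim <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  structure(
    list(data = m, fs = hdr$fs,
         time_ms = seq(hdr$window_ms[1], hdr$window_ms[2], length.out = hdr$n_samples),
         condition = hdr$condition, participant_id = hdr$participant_id),
    class = "emg_trials"
  )
}
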