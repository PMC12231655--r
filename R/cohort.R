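#' Cohort specification for the synthetic study
#'
#' Group-level means and SDs for every participant-level parameter, the
#' number of inverted-slope participants, and a master seed. Per-participant
#' parameters are placed at deterministic stratified normal quantiles
#' (participant of rank i out of N sits at quantile (i - 0.5)/N) scaled to
#' the group mean and SD, so the realized cohort mean of every true
#' parameter equals the group mean exactly. Strictly positive parameters
#' (MEP amplitudes) are stratified on the log scale and rescaled
#' multiplicatively, preserving positivity and the exact arithmetic mean.
#' Ranks are assigned to participants through independent seeded
#' permutations per field, so a participant extreme in one parameter is not
#' automatically extreme in the others.
#'
#' @param n_eeg Number of EEG (listening) participants.
#' @param n_mep Number of MEP participants.
#' @param eeg Named list of `c(mean, sd)` pairs for the EEG fields
#'   `trough_time_ms`, `peak_time_ms`, `trough_itc`, `peak_itc`,
#'   `alpha_freq_hz`; scalar fields `beta_itc`, `n_trials`, `noise_sd_uV`.
#'   Defaults are the group calibration of the emulated study.
#' @param emg Named list for the EMG side: `mean_amp_mV` (named 3-vector of
#'   condition means), `amp_sd_mV` (named 3-vector of across-participant
#'   SDs), `c(mean, sd)` for `mep_latency_ms`, scalars `amp_cv`, `n_trials`,
#'   `artifact_fraction`, `outlier_fraction`.
#' @param n_inverted_slope Number of participants generated with their
#'   trough/peak ITC values swapped (negative-slope profiles); must not
#'   exceed `n_eeg`.
#' @param master_seed Integer master seed; all per-participant seeds and the
#'   rank permutations derive from it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_eeg = 27, n_mep = 19,
                        eeg = list(trough_time_ms = c(-156.48, 40.62),
                                   peak_time_ms = c(46.41, 39.02),
                                   trough_itc = c(0.06, 0.02),
                                   peak_itc = c(0.11, 0.03),
                                   alpha_freq_hz = c(10.5, 0.8),
                                   beta_itc = 0.12,
                                   n_trials = 100,
                                   noise_sd_uV = 30),
                        emg = list(mean_amp_mV = c(setms = 3.08, standard = 2.44,
                                                   auditory_control = 2.38),
                                   amp_sd_mV = c(setms = 1.68, standard = 1.65,
                                                 auditory_control = 1.56),
                                   mep_latency_ms = c(23, 2),
                                   amp_cv = 0.5,
                                   n_trials = 125,
                                   artifact_fraction = 0.05,
                                   outlier_fraction = 0.01),
                        n_inverted_slope = 1, master_seed = 0L) {
  stopifnot(n_eeg >= 0, n_mep >= 0, n_inverted_slope >= 0,
            n_inverted_slope <= max(n_eeg, 1))
  structure(list(n_eeg = n_eeg, n_mep = n_mep, eeg = eeg, emg = emg,
                 n_inverted_slope = n_inverted_slope,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Deterministic stratified normal quantiles: mean is exact by symmetry.
stratified_normal <- function(n, mean, sd) {
  z <- stats::qnorm((seq_len(n) - 0.5) / n)
  mean + sd * z
}

# Log-scale stratification for positive parameters; multiplicative rescale
# makes the arithmetic mean exact while preserving positivity.
stratified_lognormal <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s <- sqrt(log(1 + (sd / mean)^2))
  v <- exp(s * stats::qnorm((seq_len(n) - 0.5) / n))
  v * mean / mean(v)
}

# Spread c(mean, sd) or scalar spec entries.
field_ms <- function(x) if (length(x) == 2L) x else c(x, 0)

derive_seed <- function(master, i, stream) {
  as.integer((as.numeric(master) * 10007 + 7919 * i + 104729 * stream) %% 2147483646 + 1)
}

#' Generate a synthetic cohort with exact group-level ground truth
#'
#' Materializes the per-participant ground-truth parameter tables for the
#' EEG and MEP arms of the study from a [cohort_spec()]. Exactly
#' `n_inverted_slope` participants -- those with the largest peak-minus-trough
#' ITC gaps, so the inversion is detectable above the ITC estimation noise --
#' have their trough/peak ITC values swapped. Datasets themselves are
#' generated deterministically per participant via [cohort_eeg()] /
#' [cohort_emg()] (participant-at-a-time, so a 27-participant cohort never
#' has to be held in memory at once).
#'
#' @param spec A [cohort_spec()] object.
#' @return A `cohort` object: list with `spec`, `eeg_truth` (data frame, one
#'   row per EEG participant), `emg_truth` (one row per MEP participant).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ne <- spec$n_eeg; nm <- spec$n_mep
  eeg_truth <- NULL
  if (ne > 0) {
    perm <- function(stream) {
      with_preserved_seed(derive_seed(spec$master_seed, 0L, stream), sample.int(ne))
    }
    tt <- field_ms(spec$eeg$trough_time_ms); pt <- field_ms(spec$eeg$peak_time_ms)
    ti <- field_ms(spec$eeg$trough_itc); pi_ <- field_ms(spec$eeg$peak_itc)
    af <- field_ms(spec$eeg$alpha_freq_hz)
    trough_time <- stratified_normal(ne, tt[1], tt[2])[perm(1L)]
    peak_time <- stratified_normal(ne, pt[1], pt[2])[perm(2L)]
    # ITC levels share one rank permutation (comonotone) so trough <= peak
    # holds for every participant by construction
    itc_rank <- perm(3L)
    trough_itc <- stratified_normal(ne, ti[1], ti[2])[itc_rank]
    peak_itc <- stratified_normal(ne, pi_[1], pi_[2])[itc_rank]
    if (any(trough_itc < 0) || any(peak_itc > 1) || any(peak_itc < trough_itc)) {
      stop("EEG cohort spec places ITC targets outside [0, 1] or below the trough")
    }
    alpha_freq <- stratified_normal(ne, af[1], af[2])[perm(4L)]
    inverted <- rank(-(peak_itc - trough_itc), ties.method = "first") <= spec$n_inverted_slope
    sw_t <- ifelse(inverted, peak_itc, trough_itc)
    sw_p <- ifelse(inverted, trough_itc, peak_itc)
    eeg_truth <- data.frame(
      participant = sprintf("E%02d", seq_len(ne)),
      trough_time_ms = trough_time, peak_time_ms = peak_time,
      trough_itc = sw_t, peak_itc = sw_p, inverted = inverted,
      alpha_freq_hz = alpha_freq,
      beta_itc = spec$eeg$beta_itc, n_trials = spec$eeg$n_trials,
      noise_sd_uV = spec$eeg$noise_sd_uV,
      seed = vapply(seq_len(ne), function(i) derive_seed(spec$master_seed, i, 10L), integer(1)),
      stringsAsFactors = FALSE
    )
  }
  emg_truth <- NULL
  if (nm > 0) {
    permm <- function(stream) {
      with_preserved_seed(derive_seed(spec$master_seed, 0L, stream), sample.int(nm))
    }
    means <- spec$emg$mean_amp_mV; sds <- spec$emg$amp_sd_mV
    amp_rank <- permm(5L)    # condition means comonotone within participant
    lat <- field_ms(spec$emg$mep_latency_ms)
    emg_truth <- data.frame(
      participant = sprintf("M%02d", seq_len(nm)),
      amp_setms = stratified_lognormal(nm, means[["setms"]], sds[["setms"]])[amp_rank],
      amp_standard = stratified_lognormal(nm, means[["standard"]], sds[["standard"]])[amp_rank],
      amp_auditory_control = stratified_lognormal(nm, means[["auditory_control"]],
                                                  sds[["auditory_control"]])[amp_rank],
      mep_latency_ms = stratified_normal(nm, lat[1], lat[2])[permm(6L)],
      amp_cv = spec$emg$amp_cv, n_trials = spec$emg$n_trials,
      artifact_fraction = spec$emg$artifact_fraction,
      outlier_fraction = spec$emg$outlier_fraction,
      seed = vapply(seq_len(nm), function(i) derive_seed(spec$master_seed, i, 20L), integer(1)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(spec = spec, eeg_truth = eeg_truth, emg_truth = emg_truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d EEG + %d MEP participants (master seed %d, %d inverted slope)\n",
              x$spec$n_eeg, x$spec$n_mep, x$spec$master_seed, x$spec$n_inverted_slope))
  invisible(x)
}

#' Generate the EEG dataset of one cohort participant
#'
#' @param cohort A [gen_cohort()] object.
#' @param i Participant index (row of `eeg_truth`).
#' @param ... Passed to [gen_eeg_epochs()] (e.g. `fs`, `channels`).
#' @return An [eeg_epochs()] object.
#' @export
cohort_eeg <- function(cohort, i, ...) {
  stopifnot(inherits(cohort, "cohort"))
  r <- cohort$eeg_truth[i, ]
  p <- eeg_params(trough_time_ms = r$trough_time_ms, peak_time_ms = r$peak_time_ms,
                  trough_itc = r$trough_itc, peak_itc = r$peak_itc,
                  alpha_freq_hz = r$alpha_freq_hz, beta_itc = r$beta_itc,
                  n_trials = r$n_trials, noise_sd_uV = r$noise_sd_uV,
                  inverted = r$inverted, seed = r$seed)
  gen_eeg_epochs(p, ...)
}

#' Generate the EMG trial sets of one cohort participant
#'
#' @param cohort A [gen_cohort()] object.
#' @param i Participant index (row of `emg_truth`).
#' @param conditions Conditions to generate.
#' @param ... Passed to [gen_emg_trials()] (e.g. `fs`).
#' @return Named list of `emg_trials`, one per condition.
#' @export
cohort_emg <- function(cohort, i,
                       conditions = c("setms", "standard", "auditory_control"), ...) {
  stopifnot(inherits(cohort, "cohort"))
  r <- cohort$emg_truth[i, ]
  out <- lapply(conditions, function(cd) {
    p <- emg_params(mean_amp_mV = c(setms = r$amp_setms, standard = r$amp_standard,
                                    auditory_control = r$amp_auditory_control),
                    amp_cv = r$amp_cv, mep_latency_ms = r$mep_latency_ms,
                    n_trials = r$n_trials, artifact_fraction = r$artifact_fraction,
                    outlier_fraction = r$outlier_fraction,
                    seed = derive_seed(r$seed, match(cd, c("setms", "standard", "auditory_control")), 30L))
    gen_emg_trials(p, condition = cd, participant_id = r$participant, ...)
  })
  names(out) <- conditions
  out
}
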