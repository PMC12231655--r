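window_idx <- function(time_ms, lo, hi, open = FALSE) {
  if (open) which(time_ms > lo + 1e-9 & time_ms < hi - 1e-9)
  else which(time_ms >= lo - 1e-9 & time_ms <= hi + 1e-9)
}

#' Baseline-correct EMG trials
#'
#' Subtracts each trial's mean over the pre-pulse window [-20, -5] ms from
#' the entire trial.
#'
#' @param trials An `emg_trials` object (or trials x samples matrix with a
#'   `time_ms` argument).
#' @param time_ms Sample times (taken from the object if omitted).
#' @param window_ms Baseline window, default `c(-20, -5)`.
#' @return Same type as the input, baseline corrected.
#' @export
baseline_correct <- function(trials, time_ms = NULL, window_ms = c(-20, -5)) {
  m <- if (inherits(trials, "emg_trials")) trials$data else trials
  if (is.null(time_ms)) time_ms <- trials$time_ms
  sel <- window_idx(time_ms, window_ms[1], window_ms[2])
  if (length(sel) == 0L) stop("baseline window not covered by the trial window")
  m <- m - rowMeans(m[, sel, drop = FALSE])
  if (inherits(trials, "emg_trials")) { trials$data <- m; trials } else m
}

#' Flag trials with pre-pulse muscle activity by the RMS rule
#'
#' Computes each trial's root-mean-square amplitude over [-200, +13] ms
#' around the pulse, omitting the open interval (-5, +5) ms to avoid the
#' pulse artifact, and flags trials whose RMS exceeds the block mean by more
#' than 2.5 block SDs (one-sided high: quiescent trials are unremarkable).
#' Block statistics are computed over all trials in the set.
#'
#' @param trials `emg_trials` or trials x samples matrix.
#' @param time_ms Sample times.
#' @param sd_mult Rejection threshold in block SDs.
#' @return Logical vector (TRUE = reject), with per-trial RMS as the `rms`
#'   attribute.
#' @export
rms_reject <- function(trials, time_ms = NULL, sd_mult = 2.5) {
  m <- if (inherits(trials, "emg_trials")) trials$data else trials
  if (is.null(time_ms)) time_ms <- trials$time_ms
  if (nrow(m) < 3L) stop("RMS rejection needs at least 3 trials")
  sel <- setdiff(window_idx(time_ms, -200, 13), window_idx(time_ms, -5, 5, open = TRUE))
  if (length(sel) == 0L) stop("RMS window not covered by the trial window")
  rms <- sqrt(rowMeans(m[, sel, drop = FALSE]^2))
  flag <- rms > mean(rms) + sd_mult * stats::sd(rms)
  attr(flag, "rms") <- rms
  flag
}

#' Check a trial for a biphasic MEP in the 15-40 ms window
#'
#' A trial passes if, within [15, 40] ms post-pulse, the trace contains both
#' a positive and a negative excursion each exceeding `k` times the trial's
#' pre-stimulus noise SD (computed over [-200, -20] ms), at distinct
#' samples. The k-sigma operationalization of "biphasic" is a documented
#' choice with default k = 3.
#'
#' @param trial Numeric vector (one trial), or `emg_trials` (vectorized over
#'   rows, returning a logical vector).
#' @param time_ms Sample times.
#' @param k Excursion threshold in pre-stimulus noise SDs.
#' @return Logical (TRUE = biphasic signal present).
#' @export
biphasic_check <- function(trial, time_ms = NULL, k = 3) {
  if (inherits(trial, "emg_trials")) {
    tm <- trial$time_ms
    return(apply(trial$data, 1L, biphasic_check, time_ms = tm, k = k))
  }
  if (is.null(time_ms)) stop("'time_ms' required for a bare trial vector")
  win <- window_idx(time_ms, 15, 40)
  pre <- window_idx(time_ms, -200, -20)
  if (length(win) == 0L || length(pre) == 0L) stop("required windows not covered")
  sig <- stats::sd(trial[pre])
  v <- trial[win]
  thr <- k * sig
  i_max <- which.max(v); i_min <- which.min(v)
  v[i_max] > thr && v[i_min] < -thr && i_max != i_min
}

#' Flag amplitude outliers among surviving trials
#'
#' Single pass: flags peak-to-peak amplitudes strictly greater than the mean
#' plus `sd_mult` SDs, both computed over the surviving trials supplied.
#'
#' @param p2p Numeric vector of peak-to-peak amplitudes (>= 3 values).
#' @param sd_mult Threshold in SDs (default 5).
#' @return Logical vector (TRUE = outlier).
#' @export
outlier_reject <- function(p2p, sd_mult = 5) {
  if (length(p2p) < 3L) stop("outlier rejection needs at least 3 surviving trials")
  p2p > mean(p2p) + sd_mult * stats::sd(p2p)
}

#' Peak-to-peak MEP amplitude
#'
#' Min-to-max voltage over the closed [18, 50] ms post-pulse window.
#'
#' @param trial Numeric vector, or `emg_trials` (vectorized over rows).
#' @param time_ms Sample times.
#' @param window_ms Measurement window.
#' @return Peak-to-peak amplitude(s), >= 0.
#' @export
peak_to_peak <- function(trial, time_ms = NULL, window_ms = c(18, 50)) {
  if (inherits(trial, "emg_trials")) {
    sel <- window_idx(trial$time_ms, window_ms[1], window_ms[2])
    v <- trial$data[, sel, drop = FALSE]
    return(apply(v, 1L, max) - apply(v, 1L, min))
  }
  if (is.null(time_ms)) stop("'time_ms' required for a bare trial vector")
  sel <- window_idx(time_ms, window_ms[1], window_ms[2])
  if (length(sel) == 0L) stop("peak-to-peak window not covered")
  max(trial[sel]) - min(trial[sel])
}

#' Run the full MEP preprocessing and quantification chain
#'
#' Fixed order: baseline correction, RMS pre-activation rejection, biphasic
#' check, amplitude outlier rejection, peak-to-peak quantification. Each
#' trial receives exactly one rejection reason (`none`, `rms`,
#' `not_biphasic`, `outlier`) -- the first stage that rejects it. Set-level
#' statistics use kept trials only.
#'
#' @param trials An `emg_trials` object.
#' @param k_biphasic Biphasic excursion threshold in noise SDs.
#' @param rms_sd_mult,outlier_sd_mult Rejection thresholds.
#' @return A `mep_result` object: list with `audit` (per-trial data frame:
#'   `trial`, `condition`, `reject_reason`, `kept`, `p2p_mV`), `mean_p2p`,
#'   `sd_p2p`, `n_kept`, `n_rejected`, `fraction_rejected`,
#'   `pre_pulse_abs_mean_mV` (absolute mean over [-20, -5] ms before
#'   baseline correction, kept trials).
#' @export
mep_filter_chain <- function(trials, k_biphasic = 3, rms_sd_mult = 2.5,
                             outlier_sd_mult = 5) {
  stopifnot(inherits(trials, "emg_trials"))
  n <- nrow(trials$data)
  pre_sel <- window_idx(trials$time_ms, -20, -5)
  pre_abs <- rowMeans(abs(trials$data[, pre_sel, drop = FALSE]))
  bc <- baseline_correct(trials)
  reason <- rep("none", n)
  rms_flag <- rms_reject(bc, sd_mult = rms_sd_mult)
  reason[rms_flag] <- "rms"
  surv <- reason == "none"
  bi_ok <- rep(NA, n)
  bi_ok[surv] <- apply(bc$data[surv, , drop = FALSE], 1L, biphasic_check,
                       time_ms = bc$time_ms, k = k_biphasic)
  reason[surv & !bi_ok] <- "not_biphasic"
  p2p <- peak_to_peak(bc)
  surv <- reason == "none"
  if (sum(surv) >= 3L) {
    out_flag <- outlier_reject(p2p[surv], sd_mult = outlier_sd_mult)
    reason[which(surv)[out_flag]] <- "outlier"
  }
  kept <- reason == "none"
  audit <- data.frame(trial = seq_len(n), condition = trials$condition,
                      reject_reason = reason, kept = kept, p2p_mV = p2p,
                      stringsAsFactors = FALSE)
  structure(
    list(audit = audit,
         participant_id = trials$participant_id, condition = trials$condition,
         mean_p2p = mean(p2p[kept]), sd_p2p = stats::sd(p2p[kept]),
         n_kept = sum(kept), n_rejected = sum(!kept),
         fraction_rejected = mean(!kept),
         pre_pulse_abs_mean_mV = mean(pre_abs[kept])),
    class = "mep_result"
  )
}

#' @export
print.mep_result <- function(x, ...) {
  cat(sprintf("<mep_result> %s %s: %d kept / %d rejected, mean p2p %.3f mV (SD %.3f)\n",
              x$participant_id, x$condition, x$n_kept, x$n_rejected,
              x$mean_p2p, x$sd_p2p))
  invisible(x)
}

#' Percent change between condition means
#'
#' `100 * (a - b) / b`, e.g. ((seTMS - standard) / standard) x 100.
#'
#' @param a_mean,b_mean Condition means; `b_mean` must be nonzero.
#' @return Percent change.
#' @export
percent_change <- function(a_mean, b_mean) {
  if (any(b_mean == 0)) stop("reference mean must be nonzero")
  100 * (a_mean - b_mean) / b_mean
}

#' Compare two conditions across participants
#'
#' Paired t test on per-participant condition means, the percent change of
#' the group means, and the cohort mean and median of the per-participant
#' percent changes (the latter is the quantity usually quoted, and is
#' generally larger than the percent change of the means when individual
#' gains are right-skewed).
#'
#' @param a,b Per-participant mean amplitudes (paired, same order), `a` the
#'   condition of interest (e.g. seTMS), `b` the reference.
#' @return List with `t` (paired test row), `percent_change_of_means`,
#'   `mean_percent_change`, `median_percent_change`, `per_participant`
#'   (percent changes).
#' @export
compare_conditions <- function(a, b) {
  if (length(a) != length(b)) stop("conditions must be paired")
  pc <- percent_change(a, b)
  list(t = paired_t(a, b),
       percent_change_of_means = percent_change(mean(a), mean(b)),
       mean_percent_change = mean(pc),
       median_percent_change = stats::median(pc),
       per_participant = pc)
}

#' Write a per-trial MEP audit to TSV
#' @param result A `mep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mep_audit_tsv <- function(result, path) {
  utils::write.table(result$audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
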