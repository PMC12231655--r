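#' Construct an EEG epochs container
#'
#' Channels x samples x trials array of beat-locked EEG, with a uniform
#' beat-relative time axis (0 = strong beat onset).
#'
#' @param data Numeric array, channels x samples x trials (microvolts).
#' @param fs Sampling rate in Hz.
#' @param time_ms Beat-relative sample times in ms, length `dim(data)[2]`,
#'   strictly increasing and uniform.
#' @param channel_names Character vector of channel labels (extended 10-20).
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, fs, time_ms, channel_names) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(time_ms) != dim(data)[2]) stop("'time_ms' length must match sample dimension")
  if (length(channel_names) != dim(data)[1]) stop("'channel_names' length must match channel dimension")
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6) stop("'time_ms' must be strictly increasing and uniform")
  if (anyNA(data)) stop("epoch data must not contain missing values")
  structure(
    list(data = data, fs = fs, time_ms = as.numeric(time_ms),
         channel_names = as.character(channel_names)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d channels x %d samples x %d trials @ %g Hz, window [%g, %g] ms\n",
              d[1], d[2], d[3], x$fs, min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Zero-phase (forward-backward) IIR filtering of one series
#'
#' Reference time-domain implementation: odd-reflection padding of `n_pad`
#' samples, a forward pass of the filter, time reversal, a second pass, and
#' reversal back. Used by [resample_series()] and as the oracle against
#' which the frequency-domain path of [bandpass()] is tested.
#'
#' @param x Numeric vector.
#' @param filt A filter object accepted by `signal::filter` (e.g. from
#'   `signal::butter`).
#' @param n_pad Reflection padding length in samples (capped at
#'   `length(x) - 1`); use about three time constants of the slowest filter
#'   corner to absorb IIR edge transients.
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_filter <- function(x, filt, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  xp <- c(2 * x[1] - x[(n_pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - n_pad)])
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  as.numeric(y[(n_pad + 1L):(n_pad + n)])
}

#' Band-pass filter a multichannel series
#'
#' Zero-phase 4th-order Butterworth band limitation: a high-pass at `low` Hz
#' cascaded with a low-pass at `high` Hz, each applied forward and backward
#' so the phase response cancels and the effective amplitude response is the
#' *squared* Butterworth magnitude. The zero-phase cascade is applied in the
#' frequency domain (multiplication by `|H_hp|^2 |H_lp|^2`, the exact
#' transfer function of the forward-backward pass) over odd-reflection
#' padding of three high-pass time constants, which suppresses edge
#' transients; all channels are transformed in one FFT batch.
#' [zero_phase_filter()]-based time-domain application gives the same result
#' away from the edges and serves as the reference implementation in tests.
#'
#' @param x Numeric vector, or a channels x samples matrix.
#' @param fs Sampling rate in Hz; must exceed `2 * high`.
#' @param low High-pass corner frequency in Hz.
#' @param high Low-pass corner frequency in Hz.
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, fs, low = 1, high = 49) {
  if (fs <= 2 * high) stop("sampling rate too low for the requested low-pass corner")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  ns <- ncol(x)
  n_pad <- min(ns - 1L, as.integer(ceiling(3 * fs / low)))
  xp <- cbind(2 * x[, 1] - x[, (n_pad + 1L):2L, drop = FALSE],
              x,
              2 * x[, ns] - x[, (ns - 1L):(ns - n_pad), drop = FALSE])
  nfft <- stats::nextn(ncol(xp), c(2, 3, 5))
  xp <- cbind(xp, matrix(0, nrow(xp), nfft - ncol(xp)))
  g <- bandpass_gain(seq(0, nfft - 1) / nfft * fs, fs, low, high)
  Y <- stats::mvfft(t(xp)) * g
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
  res <- t(out[(n_pad + 1L):(n_pad + ns), , drop = FALSE])
  if (vec) as.numeric(res) else res
}

#' Evaluate the zero-phase band-pass magnitude response
#'
#' Returns the amplitude gain of [bandpass()] at the requested frequencies:
#' the product of the squared magnitudes of the 4th-order Butterworth
#' high-pass and low-pass sections (each applied forward and backward).
#' Useful as an analytic oracle for attenuation checks.
#'
#' @param f_hz Frequencies at which to evaluate, in Hz.
#' @inheritParams bandpass
#' @return Numeric vector of amplitude gains in [0, 1].
#' @export
bandpass_gain <- function(f_hz, fs, low = 1, high = 49) {
  hp <- signal::butter(4, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  zi <- exp(-1i * 2 * pi * f_hz / fs)
  poly_eval <- function(cf) {        # Horner in z^-1, vectorized over frequency
    acc <- rep(cf[length(cf)] + 0i, length(zi))
    for (j in (length(cf) - 1L):1L) acc <- acc * zi + cf[j]
    acc
  }
  g <- function(filt) Mod(poly_eval(filt$b) / poly_eval(filt$a))^2  # forward + backward
  g(hp) * g(lp)
}

#' Resample a series to a lower sampling rate
#'
#' Anti-aliased downsampling: a zero-phase 4th-order Butterworth low-pass at
#' 80% of the target Nyquist frequency, followed by linear interpolation onto
#' the target sample grid. `target_fs == fs` returns the input unchanged;
#' upsampling is an error.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param fs Current sampling rate in Hz.
#' @param target_fs Target sampling rate in Hz (<= `fs`).
#' @return Resampled data; length scales by `target_fs/fs`.
#' @export
resample_series <- function(x, fs, target_fs = 1000) {
  if (target_fs > fs) stop("upsampling is not supported (target_fs > fs)")
  if (target_fs == fs) return(x)
  aa <- signal::butter(4, 0.8 * (target_fs / 2) / (fs / 2), type = "low")
  n_pad <- as.integer(ceiling(3 * fs / target_fs))
  f1 <- function(v) {
    v <- zero_phase_filter(v, aa, n_pad)
    n_out <- floor(length(v) * target_fs / fs)
    t_out <- (seq_len(n_out) - 1) / target_fs
    stats::approx(x = (seq_along(v) - 1) / fs, y = v, xout = t_out)$y
  }
  if (is.matrix(x)) t(apply(x, 1L, f1)) else f1(x)
}

#' Re-reference epochs to the channel average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that the channel mean is zero at every sample of every trial.
#'
#' @param epochs An [eeg_epochs()] object (or channels x samples matrix).
#' @return Same type as the input, average-referenced.
#' @export
rereference_average <- function(epochs) {
  if (is.matrix(epochs)) {
    if (nrow(epochs) < 2L) stop("average reference requires at least 2 channels")
    return(sweep(epochs, 2L, colMeans(epochs)))
  }
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[1] < 2L) stop("average reference requires at least 2 channels")
  m <- apply(epochs$data, c(2L, 3L), mean)
  epochs$data <- epochs$data - aperm(array(m, c(dim(epochs$data)[2:3], dim(epochs$data)[1])),
                                     c(3L, 1L, 2L))
  epochs
}

#' Cut beat-locked epochs from a continuous recording
#'
#' Extracts fixed windows around event (strong beat) times from a continuous
#' multichannel series. Events whose window would fall outside the recording
#' are dropped; the number dropped is reported via a message and stored in
#' the `n_dropped` attribute.
#'
#' @param x Channels x samples matrix (continuous recording; single channel
#'   may be given as a vector).
#' @param fs Sampling rate in Hz.
#' @param event_times_s Event onset times in seconds from recording start.
#' @param window_ms Epoch window around each event, default `c(-800, 800)`;
#'   wider than the analysis windows so wavelet edge effects can be cropped.
#' @param channel_names Channel labels.
#' @return An [eeg_epochs()] object.
#' @export
epoch_series <- function(x, fs, event_times_s, window_ms = c(-800, 800),
                         channel_names = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(x)))
  i0 <- round(window_ms[1] / 1000 * fs)
  i1 <- round(window_ms[2] / 1000 * fs)
  rel <- i0:i1
  centers <- round(event_times_s * fs) + 1L
  ok <- centers + i0 >= 1L & centers + i1 <= ncol(x)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) message(sprintf("epoch_series: dropped %d out-of-bounds event(s)", n_dropped))
  centers <- centers[ok]
  if (length(centers) == 0L) stop("no events with a complete epoch window inside the recording")
  dat <- array(0, c(nrow(x), length(rel), length(centers)))
  for (k in seq_along(centers)) dat[, , k] <- x[, centers[k] + rel, drop = FALSE]
  out <- eeg_epochs(dat, fs, rel / fs * 1000, channel_names)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write epochs as a delimited matrix with a JSON sidecar header
#'
#' Plain-text epoch interchange format: a TSV whose rows are (trial, channel)
#' slices in trial-major order and whose columns are samples, plus a JSON
#' sidecar (`<path>.json`) holding `fs`, `time_ms` range, `channel_names`,
#' and `n_trials`.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_epochs_delim <- function(epochs, path) {
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), nrow = d[1] * d[3], byrow = TRUE)
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  hdr <- list(fs = epochs$fs, window_ms = range(epochs$time_ms),
              n_samples = d[2], channel_names = epochs$channel_names,
              n_channels = d[1], n_trials = d[3], order = "trial_major")
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read epochs written by [write_epochs_delim()]
#' @param path TSV path (sidecar read from `paste0(path, ".json")`).
#' @return An [eeg_epochs()] object.
#' @export
read_epochs_delim <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dat <- aperm(array(t(m), c(hdr$n_samples, hdr$n_channels, hdr$n_trials)), c(2L, 1L, 3L))
  eeg_epochs(dat, hdr$fs, seq(hdr$window_ms[1], hdr$window_ms[2], length.out = hdr$n_samples),
             hdr$channel_names)
}
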