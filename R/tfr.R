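#' Build the fixed-window Morlet wavelet family
#'
#' Complex Morlet wavelets with a *fixed* 500 ms window at every frequency:
#' a complex exponential tapered by a Gaussian whose +/-3 SD support equals
#' the window (SD = window/6). Because the window is fixed, the number of
#' cycles scales linearly with frequency: `0.5 * f` cycles per wavelet
#' (3 cycles at 6 Hz, 24 at 48 Hz). Wavelets are normalized to unit energy
#' (sum of squared magnitudes = 1); intertrial coherence is invariant to this
#' choice and spectral perturbation is baseline-relative, so the
#' normalization only fixes the absolute power scale.
#'
#' @param freqs_hz Analysis frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param window_ms Wavelet window (full support) in ms.
#' @return List with `freqs_hz`, `fs`, `window_ms`, `half_len` (samples), and
#'   `wavelets` (complex matrix, `2*half_len+1` x `length(freqs_hz)`).
#' @export
morlet_wavelets <- function(freqs_hz, fs, window_ms = 500) {
  half_len <- round(window_ms / 2000 * fs)
  t_s <- (-half_len:half_len) / fs
  sigma_t <- (window_ms / 1000) / 6
  env <- exp(-t_s^2 / (2 * sigma_t^2))
  w <- vapply(freqs_hz, function(f) {
    h <- env * exp(2i * pi * f * t_s)
    h / sqrt(sum(Mod(h)^2))
  }, complex(length(t_s)))
  list(freqs_hz = freqs_hz, fs = fs, window_ms = window_ms,
       half_len = half_len, sigma_t_s = sigma_t, wavelets = w)
}

#' Morlet time-frequency decomposition of beat-locked epochs
#'
#' Convolves every channel/trial with the fixed-window Morlet family
#' ([morlet_wavelets()]) on a linear frequency grid and returns complex
#' coefficients on a decimated output time grid. Output times are restricted
#' so the full wavelet window fits inside the epoch (no zero-padded edges).
#'
#' The default path computes the convolution by FFT; `method = "conv"` uses
#' a direct time-domain inner product and exists as an independent oracle --
#' both agree to near machine precision.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param freqs_hz Frequency grid in Hz (linear, default 6-48 in 1 Hz steps).
#' @param window_ms Fixed wavelet window in ms.
#' @param step_ms Output time-grid step in ms (default 10).
#' @param channels Channel names to decompose (default: all).
#' @param method `"fft"` or `"conv"`.
#' @return A `tfr_coeffs` object: list with `coeffs` (complex array
#'   freq x time x trial x channel), `freqs_hz`, `times_ms`, `channel_names`,
#'   `n_trials`.
#' @export
morlet_transform <- function(epochs, freqs_hz = seq(6, 48, by = 1),
                             window_ms = 500, step_ms = 10,
                             channels = NULL, method = c("fft", "conv")) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(channels)) channels <- epochs$channel_names
  ci <- match(channels, epochs$channel_names)
  if (anyNA(ci)) stop("unknown channel(s): ", paste(channels[is.na(ci)], collapse = ", "))
  wl <- morlet_wavelets(freqs_hz, epochs$fs, window_ms)
  L <- wl$half_len
  ns <- dim(epochs$data)[2]
  if (ns <= 2L * L) stop("epoch shorter than the wavelet window")
  dt_ms <- 1000 / epochs$fs
  valid <- (L + 1L):(ns - L)              # sample indices with full support
  tv <- epochs$time_ms[valid]
  keep <- valid[abs((tv / step_ms) - round(tv / step_ms)) < 1e-6]
  times_ms <- epochs$time_ms[keep]
  n_tr <- dim(epochs$data)[3]
  out <- array(complex(1), c(length(freqs_hz), length(times_ms), n_tr, length(ci)))
  if (method == "fft") {
    nfft <- stats::nextn(ns + 2L * L, c(2, 3, 5))
    for (c_k in seq_along(ci)) {
      X <- stats::mvfft(rbind(matrix(epochs$data[ci[c_k], , ], ns, n_tr),
                              matrix(0, nfft - ns, n_tr)))
      for (f_k in seq_along(freqs_hz)) {
        # coefficient(t) = sum_m conj(h(m)) x(t + m), m = -L..L
        g <- Conj(wl$wavelets[(2L * L + 1L):1L, f_k])
        G <- stats::fft(c(g, rep(0, nfft - length(g))))
        Y <- stats::mvfft(X * G, inverse = TRUE) / nfft
        out[f_k, , , c_k] <- Y[keep + L, , drop = FALSE]
      }
    }
  } else {
    for (c_k in seq_along(ci)) {
      Xc <- matrix(epochs$data[ci[c_k], , ], ns, n_tr)   # samples x trials
      for (f_k in seq_along(freqs_hz)) {
        h <- Conj(wl$wavelets[, f_k])
        for (t_k in seq_along(keep)) {
          seg <- Xc[(keep[t_k] - L):(keep[t_k] + L), , drop = FALSE]
          out[f_k, t_k, , c_k] <- as.vector(h %*% seg)
        }
      }
    }
  }
  structure(
    list(coeffs = out, freqs_hz = freqs_hz, times_ms = times_ms,
         channel_names = channels, n_trials = n_tr, fs = epochs$fs,
         window_ms = window_ms),
    class = "tfr_coeffs"
  )
}

#' @export
print.tfr_coeffs <- function(x, ...) {
  cat(sprintf("<tfr_coeffs> %d freqs (%g-%g Hz) x %d times ([%g, %g] ms) x %d trials x %d channels\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_ms), min(x$times_ms), max(x$times_ms),
              x$n_trials, length(x$channel_names)))
  invisible(x)
}

#' Event-related spectral perturbation (dB)
#'
#' ERSP(f, t) = 10 log10(mean-over-trials power at (f, t)) minus the log mean
#' baseline power at frequency f, where the baseline is the mean over
#' baseline *times* of the trial-mean power. The trial mean is taken before
#' the log ("log mean" convention). Power is floored at `power_floor`
#' (microvolts squared) before taking logs so degenerate zero-power inputs
#' yield a finite, documented floor instead of -Inf.
#'
#' @param coeffs A `tfr_coeffs` object from [morlet_transform()].
#' @param baseline_ms Baseline window in ms, default `c(-500, -200)`
#'   (pre-beat, clear of the beat-locked response).
#' @param power_floor Minimum power before the log.
#' @return A `tfr_map` object: freq x time x channel array of dB values with
#'   `freqs_hz`, `times_ms`, `channel_names` attributes.
#' @export
ersp <- function(coeffs, baseline_ms = c(-500, -200), power_floor = 1e-20) {
  stopifnot(inherits(coeffs, "tfr_coeffs"))
  bl <- which(coeffs$times_ms >= baseline_ms[1] & coeffs$times_ms <= baseline_ms[2])
  if (length(bl) == 0L) stop("empty baseline window")
  pw <- Mod(coeffs$coeffs)^2
  mp <- apply(pw, c(1L, 2L, 4L), mean)               # freq x time x channel
  mp <- pmax(mp, power_floor)
  base <- apply(mp[, bl, , drop = FALSE], c(1L, 3L), mean)  # freq x channel
  db <- mp
  for (ch in seq_len(dim(mp)[3])) {
    db[, , ch] <- 10 * log10(mp[, , ch]) - 10 * log10(base[, ch])
  }
  tfr_map(db, coeffs)
}

#' Intertrial coherence (ITC)
#'
#' ITC(f, t) = | n^-1 sum_k c_k(f, t) / |c_k(f, t)| |: the length of the mean
#' unit phase vector across trials. 1 means complete phase coherence across
#' trials, 0 no coherence. Trials with a zero-magnitude coefficient at a
#' point are excluded from the mean at that point (with a message).
#'
#' @param coeffs A `tfr_coeffs` object with at least 2 trials.
#' @return A `tfr_map` object (freq x time x channel, values in [0, 1]).
#' @export
itc <- function(coeffs) {
  stopifnot(inherits(coeffs, "tfr_coeffs"))
  if (coeffs$n_trials < 2L) stop("ITC requires at least 2 trials")
  m <- Mod(coeffs$coeffs)
  zero <- m == 0
  if (any(zero)) {
    message(sprintf("itc: excluded %d zero-magnitude coefficient(s)", sum(zero)))
    m[zero] <- 1          # phasor set to 0 below, so the value is irrelevant
  }
  u <- coeffs$coeffs / m
  u[zero] <- 0 + 0i
  n_eff <- apply(!zero, c(1L, 2L, 4L), sum)
  s <- apply(u, c(1L, 2L, 4L), sum)
  tfr_map(Mod(s) / pmax(n_eff, 1L), coeffs)
}

tfr_map <- function(vals, coeffs) {
  structure(vals, class = "tfr_map",
            freqs_hz = coeffs$freqs_hz, times_ms = coeffs$times_ms,
            channel_names = coeffs$channel_names)
}

#' Average a time-frequency map over a frequency band
#'
#' Arithmetic mean over the frequency bins whose center lies in the closed
#' band, e.g. alpha `c(8, 14)` or beta `c(20, 26)`.
#'
#' @param map A `tfr_map` (freq x time x channel) or freq x time matrix with
#'   a `freqs_hz` attribute.
#' @param band_hz Closed band `c(lo, hi)` in Hz; must intersect the grid.
#' @return A `band_series` object: time series (or time x channel matrix)
#'   with `times_ms` and `band_hz` attributes.
#' @export
band_average <- function(map, band_hz) {
  freqs <- attr(map, "freqs_hz")
  sel <- which(freqs >= band_hz[1] - 1e-9 & freqs <= band_hz[2] + 1e-9)
  if (length(sel) == 0L) stop("band outside the frequency grid")
  v <- unclass(map)
  out <- if (length(dim(v)) == 3L) apply(v[sel, , , drop = FALSE], c(2L, 3L), mean)
         else colMeans(v[sel, , drop = FALSE])
  structure(out, class = "band_series", times_ms = attr(map, "times_ms"),
            band_hz = band_hz, channel_names = attr(map, "channel_names"))
}

#' Average time-frequency maps over channels
#'
#' Arithmetic mean of per-channel maps (computed per channel first, then
#' averaged), typically over the left-motor channels C5, C3, C1.
#'
#' @param map A `tfr_map` (freq x time x channel) or `band_series`
#'   (time x channel).
#' @param channels Channels to average; default: all in the map.
#' @return The channel-averaged map (freq x time matrix) or series (vector),
#'   attributes preserved.
#' @export
channel_average <- function(map, channels = NULL) {
  have <- attr(map, "channel_names")
  if (is.null(channels)) channels <- have
  ci <- match(channels, have)
  if (anyNA(ci)) stop("unknown channel(s): ", paste(channels[is.na(ci)], collapse = ", "))
  v <- unclass(map)
  if (length(dim(v)) == 3L) {
    out <- apply(v[, , ci, drop = FALSE], c(1L, 2L), mean)
    structure(out, class = "tfr_map", freqs_hz = attr(map, "freqs_hz"),
              times_ms = attr(map, "times_ms"), channel_names = NULL)
  } else if (length(dim(v)) == 2L && inherits(map, "band_series")) {
    structure(rowMeans(v[, ci, drop = FALSE]), class = "band_series",
              times_ms = attr(map, "times_ms"), band_hz = attr(map, "band_hz"),
              channel_names = NULL)
  } else {
    map
  }
}

#' Write a time-frequency map to long-format TSV
#' @param map A `tfr_map` object.
#' @param path Output path.
#' @param value_name Name for the value column (e.g. "itc", "ersp_db").
#' @return `path`, invisibly.
#' @export
write_tfr_tsv <- function(map, path, value_name = "value") {
  v <- unclass(map)
  freqs <- attr(map, "freqs_hz"); times <- attr(map, "times_ms")
  chans <- attr(map, "channel_names")
  if (length(dim(v)) == 2L || is.null(chans)) {
    df <- expand.grid(freq_hz = freqs, time_ms = times)
    df[[value_name]] <- as.vector(v)
  } else {
    df <- expand.grid(freq_hz = freqs, time_ms = times, channel = chans,
                      stringsAsFactors = FALSE)
    df[[value_name]] <- as.vector(v)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
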