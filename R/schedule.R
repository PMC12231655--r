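#' Build a metronome beat schedule
#'
#' Constructs the grid of auditory beat times for a stimulus block. Beats are
#' laid out at `60/tempo_bpm` second intervals starting at 0 s. In duple (and
#' quadruple) meter the accented *strong* beats fall on even beat indices and
#' the unaccented *weak* beats on odd indices, so the strong-beat period is
#' twice the beat period -- approximately 1 s (1 Hz) at 120 BPM, the regime
#' in which TMS pulse timing and the alpha-band phase analysis operate.
#'
#' @param tempo_bpm Tempo in beats per minute, between 30 and 300.
#' @param duration_s Block duration in seconds (> 0). Beats strictly before
#'   `duration_s` are included.
#' @param meter `"duple"` or `"quadruple"`. Both alternate strong/weak beats;
#'   the label is retained for provenance.
#' @return An object of class `beat_schedule`: a list with `tempo_bpm`,
#'   `duration_s`, `meter`, `strong_beat_times_s`, `weak_beat_times_s`.
#' @examples
#' sched <- make_beat_schedule(120, 30)
#' head(sched$strong_beat_times_s)  # 0, 1, 2, ... (1 Hz)
#' @export
make_beat_schedule <- function(tempo_bpm, duration_s, meter = c("duple", "quadruple")) {
  meter <- match.arg(meter)
  if (!is.numeric(tempo_bpm) || length(tempo_bpm) != 1L || !is.finite(tempo_bpm) ||
      tempo_bpm < 30 || tempo_bpm > 300) {
    stop("'tempo_bpm' must be a single number in [30, 300]")
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1L || !is.finite(duration_s) ||
      duration_s <= 0) {
    stop("'duration_s' must be a single positive number")
  }
  period <- 60 / tempo_bpm
  beats <- seq(0, duration_s - 1e-12, by = period)
  idx <- seq_along(beats) - 1L
  structure(
    list(
      tempo_bpm = tempo_bpm,
      duration_s = duration_s,
      meter = meter,
      strong_beat_times_s = beats[idx %% 2L == 0L],
      weak_beat_times_s = beats[idx %% 2L == 1L]
    ),
    class = "beat_schedule"
  )
}

#' @export
print.beat_schedule <- function(x, ...) {
  cat(sprintf(
    "<beat_schedule> %g BPM %s, %g s: %d strong / %d weak beats (strong period %.4f s)\n",
    x$tempo_bpm, x$meter, x$duration_s,
    length(x$strong_beat_times_s), length(x$weak_beat_times_s),
    2 * 60 / x$tempo_bpm
  ))
  invisible(x)
}

#' Synthesize metronome audio for a beat schedule
#'
#' Each beat is rendered as a 262 Hz (middle C) tone lasting 60 ms with
#' linear 10 ms rise and fall ramps. Weak beats are played at 1/10 of the
#' strong-beat amplitude. The waveform peak is normalized to `peak`.
#'
#' @param schedule A [make_beat_schedule()] object.
#' @param fs_audio Audio sampling rate in Hz (>= 8000).
#' @param tone_hz Tone frequency in Hz.
#' @param tone_dur_s Tone duration in seconds.
#' @param ramp_s Rise/fall ramp duration in seconds.
#' @param weak_ratio Weak/strong peak-amplitude ratio.
#' @param peak Peak amplitude of the normalized output (<= 1).
#' @return Numeric waveform vector with attributes `fs` (sampling rate).
#' @export
synth_metronome <- function(schedule, fs_audio = 44100, tone_hz = 262,
                            tone_dur_s = 0.060, ramp_s = 0.010,
                            weak_ratio = 0.1, peak = 0.9) {
  stopifnot(inherits(schedule, "beat_schedule"))
  if (fs_audio < 8000) stop("'fs_audio' must be at least 8000 Hz")
  beat_period <- 60 / schedule$tempo_bpm
  if (tone_dur_s > beat_period) {
    stop("tones overlap: tone duration exceeds the beat period at this tempo")
  }
  n <- ceiling(schedule$duration_s * fs_audio)
  wave <- numeric(n)
  n_tone <- round(tone_dur_s * fs_audio)
  n_ramp <- round(ramp_s * fs_audio)
  t_tone <- (seq_len(n_tone) - 1) / fs_audio
  env <- rep(1, n_tone)
  env[seq_len(n_ramp)] <- seq(0, 1, length.out = n_ramp)
  env[n_tone - seq_len(n_ramp) + 1L] <- seq(0, 1, length.out = n_ramp)
  tone <- sin(2 * pi * tone_hz * t_tone) * env
  place <- function(times, amp) {
    for (tt in times) {
      i0 <- round(tt * fs_audio) + 1L
      i1 <- min(i0 + n_tone - 1L, n)
      if (i0 <= n) wave[i0:i1] <<- wave[i0:i1] + amp * tone[seq_len(i1 - i0 + 1L)]
    }
  }
  place(schedule$strong_beat_times_s, 1)
  place(schedule$weak_beat_times_s, weak_ratio)
  m <- max(abs(wave))
  if (m > 0) wave <- wave * (peak / m)
  attr(wave, "fs") <- fs_audio
  wave
}

#' Schedule TMS pulse times against a beat schedule
#'
#' Computes TMS pulse times for one experimental condition:
#' \describe{
#'   \item{`setms`}{pulses at strong beat time − 200 ms, targeting the
#'     pre-beat window of sensorimotor alpha desynchronization.}
#'   \item{`auditory_control`}{pulses at the strong beat time itself
#'     (0 ms offset), same audio.}
#'   \item{`standard`}{no audio; the inter-stimulus-interval (ISI) sequence is
#'     copied verbatim from a paired `setms` plan so that ISI statistics are
#'     matched between conditions.}
#' }
#' Host beats are selected by stepping every k-th strong beat with k drawn
#' per gap from `k_choices` (seeded), subject to all ISIs being at least
#' `min_isi_s`; this keeps ISIs irregular while honoring the 3 s floor.
#'
#' @param schedule A [make_beat_schedule()] object (ignored for `standard`).
#' @param condition One of `"setms"`, `"auditory_control"`, `"standard"`.
#' @param n_pulses Number of pulses requested.
#' @param min_isi_s Minimum inter-stimulus interval in seconds.
#' @param seed Integer seed for the per-gap step draw.
#' @param offset_ms Pulse offset relative to the strong beat; defaults to
#'   −200 for `setms` and 0 for `auditory_control`.
#' @param paired_plan A `stimulus_plan` of condition `setms`; required for
#'   (and only used by) the `standard` condition.
#' @param k_choices Integer strong-beat step sizes to draw from.
#' @return An object of class `stimulus_plan`: list with `condition`,
#'   `offset_ms`, `pulse_times_s`, `isi_s`, `host_beat_times_s`.
#' @export
schedule_pulses <- function(schedule, condition = c("setms", "auditory_control", "standard"),
                            n_pulses = 100, min_isi_s = 3.0, seed = 1L,
                            offset_ms = NULL, paired_plan = NULL,
                            k_choices = 3:5) {
  condition <- match.arg(condition)
  if (condition == "standard") {
    if (is.null(paired_plan) || !inherits(paired_plan, "stimulus_plan") ||
        paired_plan$condition != "setms") {
      stop("'standard' condition requires 'paired_plan' (a setms stimulus_plan) to copy ISIs from")
    }
    pulses <- paired_plan$pulse_times_s[1] + c(0, cumsum(paired_plan$isi_s))
    return(structure(
      list(condition = "standard", offset_ms = NA_real_,
           pulse_times_s = pulses, isi_s = paired_plan$isi_s,
           host_beat_times_s = NULL),
      class = "stimulus_plan"
    ))
  }
  stopifnot(inherits(schedule, "beat_schedule"))
  if (is.null(offset_ms)) offset_ms <- if (condition == "setms") -200 else 0
  strong <- schedule$strong_beat_times_s
  period <- 2 * 60 / schedule$tempo_bpm
  ks <- k_choices[k_choices * period >= min_isi_s - 1e-9]
  if (length(ks) == 0L) ks <- as.integer(ceiling(min_isi_s / period))
  idx <- integer(n_pulses)
  with_preserved_seed(seed, {
    idx[1] <- 1L
    i <- 2L
    while (i <= n_pulses) {
      step <- if (length(ks) == 1L) ks else sample(ks, 1L)
      idx[i] <- idx[i - 1L] + step
      i <- i + 1L
    }
  })
  if (idx[n_pulses] > length(strong)) {
    stop(sprintf("schedule too short: %d pulses need strong beat #%d but only %d exist",
                 n_pulses, idx[n_pulses], length(strong)))
  }
  pulses <- strong[idx] + offset_ms / 1000
  structure(
    list(condition = condition, offset_ms = offset_ms,
         pulse_times_s = pulses, isi_s = diff(pulses),
         host_beat_times_s = strong[idx]),
    class = "stimulus_plan"
  )
}

#' @export
print.stimulus_plan <- function(x, ...) {
  cat(sprintf("<stimulus_plan> %s: %d pulses, offset %s ms, ISI [%.2f, %.2f] s\n",
              x$condition, length(x$pulse_times_s),
              ifelse(is.na(x$offset_ms), "-", format(x$offset_ms)),
              min(x$isi_s), max(x$isi_s)))
  invisible(x)
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' Minimal single-channel RIFF/WAVE writer. Samples are clipped to [-1, 1]
#' and quantized to signed 16-bit little-endian PCM. Output is bit-identical
#' for identical inputs.
#'
#' @param wave Numeric vector in [-1, 1]; its `fs` attribute (or `fs`
#'   argument) gives the sampling rate.
#' @param path Output file path.
#' @param fs Sampling rate in Hz; defaults to `attr(wave, "fs")`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, fs = attr(wave, "fs")) {
  if (is.null(fs)) stop("sampling rate not given (no 'fs' attribute or argument)")
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write beat/pulse events to a TSV file
#'
#' Shared events format: columns `onset_s`, `kind` (strong|weak|pulse),
#' `condition`.
#'
#' @param schedule Optional [make_beat_schedule()] object (strong/weak rows).
#' @param plan Optional [schedule_pulses()] plan (pulse rows).
#' @param path Output path.
#' @return The events data frame, invisibly.
#' @export
write_events_tsv <- function(path, schedule = NULL, plan = NULL) {
  ev <- data.frame(onset_s = numeric(0), kind = character(0),
                   condition = character(0), stringsAsFactors = FALSE)
  if (!is.null(schedule)) {
    ev <- rbind(ev,
      data.frame(onset_s = schedule$strong_beat_times_s, kind = "strong",
                 condition = NA_character_),
      data.frame(onset_s = schedule$weak_beat_times_s, kind = "weak",
                 condition = NA_character_))
  }
  if (!is.null(plan)) {
    ev <- rbind(ev, data.frame(onset_s = plan$pulse_times_s, kind = "pulse",
                               condition = plan$condition))
  }
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}

#' Read an events TSV written by [write_events_tsv()]
#' @param path File path.
#' @return Data frame with `onset_s`, `kind`, `condition`.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Run `expr` under a fixed seed without clobbering the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  eval.parent(substitute(expr))
}
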