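test_that("beat schedules have the right grid and strong/weak alternation", {
  s <- make_beat_schedule(120, 30, "duple")
  expect_equal(s$strong_beat_times_s[1:5], 0:4)          # 1 Hz strong beats
  expect_equal(s$weak_beat_times_s[1:3], c(0.5, 1.5, 2.5))
  expect_true(all(diff(s$strong_beat_times_s) > 0))

  s98 <- make_beat_schedule(98, 30)
  expect_equal(diff(s98$strong_beat_times_s)[1], 2 * 60 / 98, tolerance = 1e-12)

  # duration shorter than one beat period: single beat at 0
  tiny <- make_beat_schedule(120, 0.3)
  expect_equal(tiny$strong_beat_times_s, 0)
  expect_length(tiny$weak_beat_times_s, 0)

  expect_error(make_beat_schedule(20, 30), "tempo")
  expect_error(make_beat_schedule(120, -1), "duration")
})

test_that("metronome tones have the specified duration, ramps and accenting", {
  s <- make_beat_schedule(120, 4)
  w <- synth_metronome(s, fs_audio = 44100)
  n_tone <- round(0.060 * 44100)
  expect_equal(n_tone, 2646)
  # strong tone occupies the first 60 ms, then silence until the weak beat
  expect_true(all(w[(n_tone + 10):(round(0.5 * 44100) - 10)] == 0))  # 440 ms gap
  # weak/strong peak ratio = 1/10
  strong_peak <- max(abs(w[1:n_tone]))
  weak_idx <- round(0.5 * 44100) + seq_len(n_tone)
  expect_equal(max(abs(w[weak_idx])) / strong_peak, 0.1, tolerance = 0.02)
  expect_lte(max(abs(w)), 1)
  # ramps: amplitude near the tone edges is far below the plateau
  edge <- max(abs(w[1:80]))
  expect_lt(edge, 0.25 * strong_peak)
})

test_that("pulse plans honor the offset and the 3 s ISI floor", {
  s <- make_beat_schedule(120, 400)
  p <- schedule_pulses(s, "setms", n_pulses = 60, seed = 4)
  # every pulse exactly 200 ms before its host strong beat
  expect_equal(p$pulse_times_s - p$host_beat_times_s, rep(-0.2, 60))
  expect_true(all(p$isi_s >= 3 - 1e-9))
  pa <- schedule_pulses(s, "auditory_control", n_pulses = 60, seed = 4)
  expect_equal(pa$pulse_times_s - pa$host_beat_times_s, rep(0, 60))

  # ISI floor over many seeds (property); 1e-9 covers float representation
  for (sd in 1:40) {
    pl <- schedule_pulses(s, "setms", n_pulses = 50, seed = sd)
    expect_gte(min(pl$isi_s), 3 - 1e-9)
  }

  # fixed k = 3 at 1 Hz strong beats: all ISIs exactly 3 s
  p3 <- schedule_pulses(s, "setms", n_pulses = 20, seed = 1, k_choices = 3)
  expect_equal(unique(round(p3$isi_s, 9)), 3)

  expect_error(schedule_pulses(make_beat_schedule(120, 20), "setms", n_pulses = 50),
               "too short")
})

test_that("standard plans copy the paired seTMS ISI sequence verbatim", {
  s <- make_beat_schedule(120, 500)
  se <- schedule_pulses(s, "setms", n_pulses = 80, seed = 11)
  st <- schedule_pulses(condition = "standard", paired_plan = se)
  expect_identical(st$isi_s, se$isi_s)
  expect_error(schedule_pulses(s, "standard"), "paired_plan")
})

test_that("WAV output is deterministic and carries correct header arithmetic", {
  s <- make_beat_schedule(120, 2)
  w <- synth_metronome(s, fs_audio = 8000)
  f1 <- tempfile(fileext = ".wav"); f2 <- tempfile(fileext = ".wav")
  write_wav(w, f1); write_wav(w, f2)
  b1 <- readBin(f1, "raw", file.info(f1)$size)
  expect_identical(b1, readBin(f2, "raw", file.info(f2)$size))
  expect_equal(length(b1), 44L + 2L * length(w))           # RIFF header + PCM16
  expect_identical(rawToChar(b1[1:4]), "RIFF")
  expect_identical(rawToChar(b1[9:16]), "WAVEfmt ")
  unlink(c(f1, f2))
})

test_that("events TSV round-trips beats and pulses", {
  s <- make_beat_schedule(120, 30)
  p <- schedule_pulses(s, "setms", n_pulses = 5, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(f, schedule = s, plan = p)
  ev <- read_events_tsv(f)
  expect_setequal(unique(ev$kind), c("strong", "weak", "pulse"))
  expect_equal(sum(ev$kind == "pulse"), 5)
  expect_equal(sort(ev$onset_s[ev$kind == "strong"]), s$strong_beat_times_s)
  unlink(f)
})
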