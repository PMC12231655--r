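# small fixture: 2 channels, 5 trials, 10 Hz + noise at 500 Hz
make_fixture <- function(seed = 42, ns = 400, fs = 500, n_tr = 5) {
  set.seed(seed)
  tm <- (seq_len(ns) - ns / 2) / fs * 1000
  dat <- array(rnorm(2 * ns * n_tr, 0, 1), c(2, ns, n_tr))
  for (k in seq_len(n_tr)) {
    dat[1, , k] <- dat[1, , k] + 2 * sin(2 * pi * 10 * tm / 1000 + k)
  }
  eeg_epochs(dat, fs, tm, c("C3", "C1"))
}

test_that("wavelets have a fixed 500 ms window with cycles scaling linearly", {
  wl <- morlet_wavelets(c(6, 10, 48), 1000)
  expect_equal(nrow(wl$wavelets), 2 * round(0.25 * 1000) + 1)   # 500 ms support
  # cycles = duration * frequency: 3 cycles at 6 Hz, 24 at 48 Hz
  expect_equal(0.5 * 6, 3)
  expect_equal(0.5 * 48, 24)
  # count zero crossings of the real part as a direct cycle check at 6 Hz
  re6 <- Re(wl$wavelets[, 1])
  crossings <- sum(diff(sign(re6[abs(re6) > 1e-12])) != 0)
  expect_equal(crossings, 6, tolerance = 1)                     # ~2 per cycle
  # unit energy
  expect_equal(colSums(Mod(wl$wavelets)^2), rep(1, 3), tolerance = 1e-12)
})

test_that("FFT and direct-convolution coefficients agree to 1e-8", {
  ep <- make_fixture()
  a <- morlet_transform(ep, freqs_hz = seq(6, 48, by = 6), step_ms = 20, method = "fft")
  b <- morlet_transform(ep, freqs_hz = seq(6, 48, by = 6), step_ms = 20, method = "conv")
  expect_lt(max(Mod(a$coeffs - b$coeffs)), 1e-8)
  expect_equal(a$times_ms, b$times_ms)
})

test_that("a pure sinusoid is a matched filter for its grid frequency", {
  fs <- 1000
  tm <- (1:1200) - 600
  dat <- array(rep(sin(2 * pi * 10 * tm / 1000), 3), c(1, 1200, 3))
  ep <- eeg_epochs(dat, fs, tm, "C3")
  tf <- morlet_transform(ep)
  pw <- apply(Mod(tf$coeffs)^2, 1, mean)
  expect_equal(tf$freqs_hz[which.max(pw)], 10)
  # wavelet power of a grid-frequency sinusoid is constant over time (< 1%)
  p10 <- Mod(tf$coeffs[which(tf$freqs_hz == 10), , 1, 1])^2
  expect_lt(diff(range(p10)) / mean(p10), 0.01)
})

test_that("ITC is exactly 1 for identical trials and 0 for antipodal pairs", {
  fs <- 1000
  tm <- (1:1200) - 600
  s <- sin(2 * pi * 10 * tm / 1000)
  ep <- eeg_epochs(array(rep(s, 20), c(1, 1200, 20)), fs, tm, "C3")
  m <- itc(morlet_transform(ep))
  expect_equal(max(abs(unclass(m) - 1)), 0, tolerance = 1e-12)

  ep2 <- eeg_epochs(array(c(s, -s), c(1, 1200, 2)), fs, tm, "C3")
  m2 <- itc(morlet_transform(ep2))
  expect_lt(max(unclass(m2)), 1e-10)
})

test_that("ITC of uniform random phases matches the Rayleigh null level", {
  # 100 replicates of 100 random-phase unit trials through the itc() op
  set.seed(31)
  fs <- 250; ns <- 300
  tm <- (seq_len(ns) - 150) / fs * 1000
  vals <- replicate(100, {
    ph <- runif(100, 0, 2 * pi)
    dat <- array(0, c(1, ns, 100))
    for (k in 1:100) dat[1, , k] <- sin(2 * pi * 10 * tm / 1000 + ph[k])
    tf <- morlet_transform(eeg_epochs(dat, fs, tm, "C3"), freqs_hz = 10, step_ms = 100)
    mean(unclass(itc(tf)))
  })
  expect_equal(mean(vals), 0.886 / sqrt(100), tolerance = 0.10)
})

test_that("ITC is invariant to per-trial amplitude scaling and bounded", {
  ep <- make_fixture()
  tf <- morlet_transform(ep, freqs_hz = seq(6, 48, by = 3), step_ms = 20)
  m1 <- itc(tf)
  tf2 <- tf
  sc <- runif(tf$n_trials, 0.1, 10)
  for (k in seq_len(tf$n_trials)) tf2$coeffs[, , k, ] <- tf2$coeffs[, , k, ] * sc[k]
  m2 <- itc(tf2)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-12)
  # bounds fuzz
  for (s in 1:5) {
    m <- itc(morlet_transform(make_fixture(seed = s, ns = 300, n_tr = 4),
                              freqs_hz = seq(6, 48, by = 6), step_ms = 50))
    expect_true(all(unclass(m) >= 0 & unclass(m) <= 1))
  }
})

test_that("ERSP self-baselines to 0 dB and reports power changes in dB", {
  # stationary signal: ERSP ~ 0 everywhere
  ep <- make_fixture(seed = 3, ns = 1000, fs = 500, n_tr = 30)
  tf <- morlet_transform(ep, freqs_hz = c(10, 20), step_ms = 50)
  e <- ersp(tf, baseline_ms = c(-500, -200))
  expect_lt(max(abs(unclass(e))), 2.5)   # stochastic, small around 0 dB

  # constructed coefficients: power doubled outside the baseline
  fake <- tf
  bl <- fake$times_ms <= -200
  fake$coeffs[, !bl, , ] <- fake$coeffs[, !bl, , ] * 0 + sqrt(2)
  fake$coeffs[, bl, , ] <- fake$coeffs[, bl, , ] * 0 + 1
  e2 <- ersp(fake, baseline_ms = c(-500, -200))
  expect_equal(unclass(e2)[1, !bl, 1], rep(10 * log10(2), sum(!bl)), tolerance = 1e-12)

  # zero-power input is floored, not -Inf
  fake$coeffs[] <- 0
  e3 <- ersp(fake, baseline_ms = c(-500, -200))
  expect_true(all(is.finite(unclass(e3))))
  expect_error(ersp(tf, baseline_ms = c(-2000, -1900)), "baseline")
})

test_that("band averaging uses closed bands on the grid; channel averaging is arithmetic", {
  ep <- make_fixture()
  tf <- morlet_transform(ep, step_ms = 50)       # full 6-48 Hz unit grid
  m <- itc(tf)
  # alpha band on a unit-spaced grid: exactly 7 bins
  expect_equal(sum(tf$freqs_hz >= 8 & tf$freqs_hz <= 14), 7L)
  a <- band_average(m, c(8, 14))
  manual <- apply(unclass(m)[tf$freqs_hz >= 8 & tf$freqs_hz <= 14, , , drop = FALSE],
                  c(2, 3), mean)
  expect_equal(unclass(a), manual, tolerance = 1e-14, ignore_attr = TRUE)
  # constant map -> constant series
  cm <- m; cm[] <- 0.4
  expect_true(all(abs(band_average(cm, c(20, 26)) - 0.4) < 1e-14))
  expect_error(band_average(m, c(100, 120)), "band")
  # channel average: mean of per-channel maps; single channel = identity
  ca <- channel_average(m, c("C3", "C1"))
  expect_equal(unclass(ca), (unclass(m)[, , 1] + unclass(m)[, , 2]) / 2,
               ignore_attr = TRUE)
  c1 <- channel_average(m, "C3")
  expect_equal(unclass(c1), unclass(m)[, , 1], ignore_attr = TRUE)
  expect_error(channel_average(m, "Oz"), "unknown")
})

test_that("TFR maps export to long-format TSV", {
  ep <- make_fixture(ns = 300)
  m <- itc(morlet_transform(ep, freqs_hz = c(10, 20), step_ms = 100))
  f <- tempfile(fileext = ".tsv")
  write_tfr_tsv(m, f, "itc")
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_named(df, c("freq_hz", "time_ms", "channel", "itc"))
  expect_equal(nrow(df), length(unclass(m)))
  unlink(f)
})
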