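test_that("band-pass keeps the passband, kills line noise and DC", {
  fs <- 1000
  t_s <- (0:(4 * fs - 1)) / fs
  x10 <- sin(2 * pi * 10 * t_s)
  y10 <- bandpass(x10, fs)
  i <- 500:3500                                   # interior, clear of edges
  expect_lt(abs(sd(y10[i]) / sd(x10[i]) - 1), 0.01)   # < 1% attenuation at 10 Hz

  x60 <- sin(2 * pi * 60 * t_s)
  y60 <- bandpass(x60, fs)
  g60 <- bandpass_gain(60, fs)
  # measured amplitude gain matches the squared-Butterworth analytic response
  expect_equal(sd(y60[i]) / sd(x60[i]), g60, tolerance = 0.01)
  # power attenuation at 60 Hz exceeds 90%
  expect_gt(1 - g60^2, 0.90)

  ydc <- bandpass(rep(2.5, 2000), fs)
  expect_lt(max(abs(ydc[200:1800])), 1e-3)        # DC removed by the 1 Hz high-pass
})

test_that("frequency-domain band-pass agrees with forward-backward filtering", {
  fs <- 1000
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.9), 3000)) + 4
  hp <- signal::butter(4, 1 / (fs / 2), "high")
  lp <- signal::butter(4, 49 / (fs / 2), "low")
  ref <- zero_phase_filter(zero_phase_filter(x, hp, 2999), lp, 2999)
  y <- bandpass(x, fs)
  i <- 400:2600
  expect_lt(max(abs(y[i] - ref[i])) / sd(x), 0.01)
})

test_that("filtering is phase-neutral (zero cross-correlation lag)", {
  fs <- 1000
  set.seed(7)
  x <- as.numeric(stats::filter(rnorm(4000), rep(1, 25), sides = 2))
  x[is.na(x)] <- 0
  y <- bandpass(x, fs)
  cc <- ccf(x[500:3500], y[500:3500], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("resampling is anti-aliased, length-scaling and identity-safe", {
  fs <- 25000
  t_s <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 10 * t_s)
  y <- resample_series(x, fs, 1000)
  expect_length(y, 1000)                           # 25 kHz, 1 s -> 1000 samples
  t2 <- (0:999) / 1000
  expect_lt(max(abs(y[100:900] - sin(2 * pi * 10 * t2)[100:900])), 0.01)
  expect_identical(resample_series(x, fs, fs), x)  # identity
  expect_error(resample_series(x, 1000, 2000), "upsampling")
})

test_that("average re-referencing zeroes the channel mean everywhere", {
  m <- rbind(c(1, -1, 1), c(-1, 1, -1))
  expect_equal(rereference_average(m), m)           # already zero-mean
  m2 <- rbind(c(2, 2), c(0, 0))
  expect_equal(rereference_average(m2), rbind(c(1, 1), c(-1, -1)))
  set.seed(1)
  big <- matrix(rnorm(64 * 500), 64)
  out <- rereference_average(big)
  expect_lt(max(abs(colMeans(out))), 1e-9)
  expect_error(rereference_average(big[1, , drop = FALSE]), "2 channels")

  # epochs method
  ep <- eeg_epochs(array(rnorm(3 * 100 * 4), c(3, 100, 4)), 100,
                   seq(-495, 495, by = 10), c("C5", "C3", "C1"))
  epr <- rereference_average(ep)
  expect_lt(max(abs(apply(epr$data, c(2, 3), mean))), 1e-9)
})

test_that("epoching cuts events, drops out-of-bounds ones with a count", {
  fs <- 1000
  x <- matrix(rnorm(2 * 10000), 2)
  ev <- c(0.5, 2, 5, 9.9)                          # first and last out of bounds
  expect_message(ep <- epoch_series(x, fs, ev, window_ms = c(-800, 800)),
                 "dropped 2")
  expect_equal(dim(ep$data)[3], 2L)
  expect_equal(attr(ep, "n_dropped"), 2L)
  expect_equal(ep$time_ms[1], -800)
  # epoch content matches the recording slice
  i0 <- round(2 * fs) + 1
  expect_equal(ep$data[1, , 1], x[1, (i0 - 800):(i0 + 800)])
})

test_that("epoch containers validate their invariants", {
  expect_error(eeg_epochs(array(0, c(2, 10, 3)), 100, 1:9, c("a", "b")), "length")
  expect_error(eeg_epochs(array(0, c(2, 10, 3)), 100, 10:1, c("a", "b")), "increasing")
  bad <- array(0, c(2, 10, 3)); bad[1, 1, 1] <- NA
  expect_error(eeg_epochs(bad, 100, 1:10, c("a", "b")), "missing")
})

test_that("delimited epoch files round-trip", {
  set.seed(2)
  ep <- eeg_epochs(array(rnorm(3 * 50 * 4), c(3, 50, 4)), 250,
                   seq(-98, 98, by = 4), c("C5", "C3", "C1"))
  f <- tempfile(fileext = ".tsv")
  write_epochs_delim(ep, f)
  ep2 <- read_epochs_delim(f)
  expect_equal(ep2$data, ep$data, tolerance = 1e-8)
  expect_identical(ep2$channel_names, ep$channel_names)
  expect_equal(ep2$fs, ep$fs)
  unlink(c(f, paste0(f, ".json")))
})
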