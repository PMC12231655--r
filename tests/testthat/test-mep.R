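mk_trials <- function(data, fs = 5000, window_ms = c(-200, 60), condition = "setms") {
  structure(list(data = data, fs = fs,
                 time_ms = seq(round(window_ms[1] * fs / 1000),
                               round(window_ms[2] * fs / 1000)) / fs * 1000,
                 condition = condition, participant_id = "T"),
            class = "emg_trials")
}

test_that("baseline correction subtracts the [-20, -5] ms mean per trial", {
  fs <- 5000
  tr <- mk_trials(matrix(0.3, 2, 1301))
  bc <- baseline_correct(tr)
  sel <- tr$time_ms >= -20 & tr$time_ms <= -5
  expect_equal(max(abs(rowMeans(bc$data[, sel]))), 0)
  expect_equal(bc$data[1, 1], 0)                        # whole trace shifted by -0.3
  # zero trace unchanged
  z <- baseline_correct(mk_trials(matrix(0, 1, 1301)))
  expect_equal(z$data, matrix(0, 1, 1301))
  # ramp: shifted by its own baseline mean, checked against direct arithmetic
  ramp <- matrix(seq(0, 1, length.out = 1301), 1, byrow = TRUE)
  rb <- baseline_correct(mk_trials(ramp))
  expect_equal(rb$data[1, ], ramp[1, ] - mean(ramp[1, sel]), tolerance = 1e-14)
})

test_that("RMS rejection flags seeded pre-activation trials exactly", {
  set.seed(21)
  fs <- 5000
  n <- 100
  dat <- matrix(rnorm(n * 1301, 0, 0.006), n)
  hot <- 1:5
  pre <- seq_len(round(200 * fs / 1000))                # the pre-pulse region
  for (k in hot) dat[k, pre] <- dat[k, pre] + rnorm(length(pre), 0, 0.06)  # 10x background
  flags <- rms_reject(mk_trials(dat))
  expect_identical(which(flags), hot)

  # identical trials: SD = 0, strict inequality keeps everything
  same <- mk_trials(matrix(1, 10, 1301))
  expect_false(any(rms_reject(same)))

  # huge values confined to the omitted (-5, +5) ms gap are ignored
  dat2 <- matrix(rnorm(20 * 1301, 0, 0.006), 20)
  gap <- abs(mk_trials(dat2)$time_ms) < 5 - 1e-9
  dat2[3, gap] <- 50
  expect_false(any(rms_reject(mk_trials(dat2))))
  expect_error(rms_reject(mk_trials(dat2[1:2, ])), "3 trials")
})

test_that("biphasic check demands opposite excursions inside 15-40 ms", {
  set.seed(14)
  fs <- 5000
  tm <- seq(-1000, 300) / 5
  mep <- mep_template(tm, latency_ms = 22, amp_mV = 1)
  noise <- rnorm(length(tm), 0, 0.006)
  expect_true(biphasic_check(mep + noise, tm))
  expect_false(biphasic_check(noise, tm))               # flat noise-only
  # monophasic single lobe fails; verified against a sign-excursion scan
  mono <- exp(-(tm - 25)^2 / 50) + rnorm(length(tm), 0, 0.001)
  win <- tm >= 15 & tm <= 40
  sig <- sd(mono[tm >= -200 & tm <= -20])
  expect_identical(biphasic_check(mono, tm),
                   max(mono[win]) > 3 * sig && min(mono[win]) < -3 * sig)
  expect_false(biphasic_check(mono, tm))
})

test_that("outlier rejection is one-sided, strict, single-pass", {
  expect_false(any(outlier_reject(rep(2, 10))))
  p2p <- c(rep(1, 99) + rnorm(99, 0, 0.01), 50)
  set.seed(2)
  expect_identical(which(outlier_reject(p2p)), 100L)
  # exactly at mean + 5 SD: not flagged (strict >)
  v <- c(1, 2, 3)
  thr <- mean(v) + 5 * sd(v)
  expect_false(any(outlier_reject(c(v, thr))[4]))
  expect_error(outlier_reject(c(1, 2)), "3 surviving")
})

test_that("peak-to-peak uses only the closed 18-50 ms window", {
  fs <- 5000
  tm <- seq(-1000, 300) / 5
  x <- numeric(length(tm))
  x[which.min(abs(tm - 30))] <- 1.2
  x[which.min(abs(tm - 35))] <- -0.8
  expect_equal(peak_to_peak(x, tm), 2.0)
  expect_equal(peak_to_peak(numeric(length(tm)), tm), 0)
  # extremes placed just outside the window are excluded
  y <- numeric(length(tm))
  y[which.min(abs(tm - 17))] <- 5
  y[which.min(abs(tm - 51))] <- -5
  y[which.min(abs(tm - 30))] <- 0.4
  y[which.min(abs(tm - 40))] <- -0.1
  sel <- tm >= 18 & tm <= 50
  expect_equal(peak_to_peak(y, tm), max(y[sel]) - min(y[sel]))
  expect_equal(peak_to_peak(y, tm), 0.5)
})

test_that("the filter chain audits every trial with a single reject reason", {
  p <- emg_params(artifact_fraction = 0.05, outlier_fraction = 0.01, seed = 33)
  tr <- gen_emg_trials(p, "standard")
  res <- mep_filter_chain(tr)
  expect_equal(nrow(res$audit), p$n_trials)
  expect_true(all(res$audit$reject_reason %in% c("none", "rms", "not_biphasic", "outlier")))
  expect_identical(res$audit$kept, res$audit$reject_reason == "none")
  expect_equal(res$n_kept + res$n_rejected, p$n_trials)
  gt <- attr(tr, "ground_truth")
  # seeded artifacts/outliers recovered with the right reasons
  expect_identical(which(res$audit$reject_reason == "rms"), which(gt$class == "artifact"))
  expect_identical(which(res$audit$reject_reason == "outlier"), which(gt$class == "outlier"))
})

test_that("artifact-free sets lose almost nothing to false positives", {
  for (s in 1:4) {
    p <- emg_params(artifact_fraction = 0, outlier_fraction = 0, seed = s)
    res <- mep_filter_chain(gen_emg_trials(p, "setms"))
    expect_lt(res$fraction_rejected, 0.05)
  }
})

test_that("clean-trial amplitudes are recovered within 2% at 150 trials", {
  p <- emg_params(n_trials = 150, artifact_fraction = 1 / 30, outlier_fraction = 1 / 150,
                  seed = 77)
  tr <- gen_emg_trials(p, "setms")
  gt <- attr(tr, "ground_truth")
  res <- mep_filter_chain(tr)
  truth <- mean(gt$true_amp_mV[gt$class == "clean"])
  expect_lt(abs(res$mean_p2p - truth) / truth, 0.02)
})

test_that("percent change follows the (a - b)/b convention and round-trips", {
  expect_equal(percent_change(3.08, 2.44), 26.22951, tolerance = 1e-5)
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(3, 2), 50)
  expect_error(percent_change(1, 0), "nonzero")
  # algebraic round trip: (1 + pc(a,b)/100) * (1 + pc(b,a)/100 inverse)
  a <- 3.7; b <- 1.9
  expect_equal((1 + percent_change(a, b) / 100) * (1 + percent_change(b, a) / 100) /
                 ((a / b) * (b / a)), 1, tolerance = 1e-12)
  expect_equal((1 + percent_change(a, b) / 100) * b, a, tolerance = 1e-12)
})

test_that("condition comparison reports paired t and percent-change summaries", {
  a <- c(2.2, 3.3); b <- c(2.0, 3.0)
  cc <- compare_conditions(a, b)
  expect_equal(cc$per_participant, c(10, 10), tolerance = 1e-12)
  cc2 <- compare_conditions(c(1.1, 1.3), c(1.0, 1.0))
  expect_equal(cc2$mean_percent_change, 20)
  expect_equal(cc2$median_percent_change, 20)
  expect_error(compare_conditions(c(1, 2), c(1, 2)), "zero-variance")
})

test_that("MEP audit TSV round-trips", {
  p <- emg_params(seed = 5, n_trials = 30, artifact_fraction = 0, outlier_fraction = 0)
  res <- mep_filter_chain(gen_emg_trials(p, "setms"))
  f <- tempfile(fileext = ".tsv")
  write_mep_audit_tsv(res, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 30)
  expect_equal(df$p2p_mV, res$audit$p2p_mV, tolerance = 1e-6)
  unlink(f)
})
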