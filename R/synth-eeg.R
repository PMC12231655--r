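#' Participant-level synthetic EEG parameters
#'
#' Ground-truth parameters for one synthetic participant's beat-locked EEG:
#' the beat-relative time and depth of the pre-beat alpha-ITC trough, the
#' post-beat peak, the individual alpha (mu) frequency, a constant beta-band
#' coherence level, trial count and broadband noise level.
#'
#' @param trough_time_ms Beat-relative trough time in ms (negative =
#'   pre-beat). Values in [-222, -99] are inside the detectable regime of the
#'   trough search window; values outside are allowed (the cohort tails fall
#'   outside) and will be clamped by detection, not by generation.
#' @param peak_time_ms Post-beat peak time in ms (detectable regime [0, 101]).
#' @param trough_itc Target measured alpha ITC at the trough, in [0, 1].
#' @param peak_itc Target measured alpha ITC at the peak, in [0, 1]. Must be
#'   >= `trough_itc` unless `inverted = TRUE`.
#' @param alpha_freq_hz Individual alpha frequency (8-14 Hz).
#' @param beta_itc Target beta-band (20-26 Hz) ITC, constant over time.
#' @param beta_freq_hz Beta frequency (20-26 Hz).
#' @param n_trials Number of epochs (>= 2).
#' @param noise_sd_uV SD of the additive broadband Gaussian noise per channel.
#' @param alpha_amp_uV Alpha (mu) component amplitude on the motor channels.
#' @param beta_amp_uV Beta component amplitude on the motor channels.
#' @param phase_diffusion Brownian phase-walk rate (rad^2/s) of the
#'   nonlocked oscillatory components; 5 gives a phase coherence time of
#'   about 0.4 s, the timescale of spontaneous mu/beta bursts. 0 freezes
#'   each trial's random phase for the whole epoch.
#' @param inverted Logical; TRUE marks a participant whose trough-window
#'   coherence exceeds the peak-window coherence (negative slope profile).
#' @param seed Integer RNG seed for this participant's data.
#' @return A `participant_eeg_params` object (validated list).
#' @export
eeg_params <- function(trough_time_ms = -156.48, peak_time_ms = 46.41,
                       trough_itc = 0.06, peak_itc = 0.11,
                       alpha_freq_hz = 10.5, beta_itc = 0.12,
                       beta_freq_hz = 23, n_trials = 100,
                       noise_sd_uV = 30, alpha_amp_uV = 10, beta_amp_uV = 5,
                       phase_diffusion = 5, inverted = FALSE, seed = 1L) {
  stopifnot(n_trials >= 2, noise_sd_uV >= 0,
            trough_itc >= 0, trough_itc <= 1, peak_itc >= 0, peak_itc <= 1,
            peak_time_ms > trough_time_ms)
  if (!inverted && trough_itc > peak_itc) {
    stop("trough_itc > peak_itc requires inverted = TRUE")
  }
  structure(as.list(environment()), class = "participant_eeg_params")
}

# Raised-cosine interpolation through control points (knot_t, knot_v).
# Smooth (C1) mixing profile with extrema exactly at the interior knots.
raised_cosine_profile <- function(t, knot_t, knot_v) {
  out <- numeric(length(t))
  out[t <= knot_t[1]] <- knot_v[1]
  out[t >= knot_t[length(knot_t)]] <- knot_v[length(knot_v)]
  for (j in seq_len(length(knot_t) - 1L)) {
    in_seg <- t > knot_t[j] & t < knot_t[j + 1L]
    if (any(in_seg)) {
      u <- (t[in_seg] - knot_t[j]) / (knot_t[j + 1L] - knot_t[j])
      s <- (1 - cos(pi * u)) / 2
      out[in_seg] <- knot_v[j] * (1 - s) + knot_v[j + 1L] * s
    }
  }
  at_knot <- match(t, knot_t)
  hit <- !is.na(at_knot)
  out[hit] <- knot_v[at_knot[hit]]
  out
}

# Mixing profile w(t): periodic, one cycle per strong beat. Each cycle has a
# symmetric raised-cosine desynchronization dip to w_trough centered at the
# trough time and a symmetric resynchronization bump to w_peak centered at
# the peak time, each of half-width (peak_time - trough_time)/2, on a flat
# baseline midway between the two levels. Steady-state entrainment repeats
# every beat, so the epoch edges carry the neighboring beats' cycles rather
# than an arbitrary plateau, and both extrema are locally symmetric (their
# detected times are unbiased).
mixing_profile <- function(time_ms, trough_time_ms, peak_time_ms, w_trough, w_peak,
                           period_ms = 1000) {
  gap <- peak_time_ms - trough_time_ms
  if (gap <= 0 || 2 * gap >= period_ms) {
    stop("need 0 < peak_time - trough_time < period/2 for the periodic profile")
  }
  hw <- gap / 2
  mid <- (w_trough + w_peak) / 2
  k_lo <- floor((min(time_ms) - peak_time_ms) / period_ms) - 1L
  k_hi <- ceiling((max(time_ms) - trough_time_ms) / period_ms) + 1L
  cyc_t <- c(trough_time_ms - hw, trough_time_ms, trough_time_ms + hw,
             peak_time_ms, peak_time_ms + hw)
  cyc_v <- c(mid, w_trough, mid, w_peak, mid)
  knot_t <- as.vector(vapply(k_lo:k_hi, function(k) cyc_t + k * period_ms,
                             numeric(length(cyc_t))))
  knot_v <- rep(cyc_v, times = k_hi - k_lo + 1L)
  raised_cosine_profile(time_ms, knot_t, knot_v)
}

# Fixed internal seed for the calibration oracle's Monte-Carlo draws, so the
# target-ITC -> w mapping is a deterministic function of its arguments.
.CAL_SEED <- 20260930L

# Session cache for calibration tables (deterministic given arguments).
.cal_cache <- new.env(parent = emptyenv())

#' Monte-Carlo response of measured ITC to the phase-locking level
#'
#' The calibration oracle behind the synthetic EEG generator. Each trial's
#' band-limited component is a mixture `w * locked + (1 - w) * random-phase`;
#' the expected ITC *measured by the analysis pipeline at a finite trial
#' count* has no convenient closed form, so it is estimated by Monte-Carlo at
#' the phasor level: per analysis frequency bin the locked and random
#' sinusoid components and the additive noise are projected through the
#' package's own Morlet wavelets (numerically computed complex gains), unit
#' phasors are averaged across `n_trials` trials, and ITC is averaged across
#' the band's bins and `n_channels_avg` analysis channels, exactly as the
#' pipeline does. The finite-n resultant floor (0.886/sqrt(n) for fully
#' random phases) is therefore built into the mapping, as is the partial
#' decoherence of the nonlocked component within the wavelet window when
#' `phase_diffusion > 0`.
#'
#' @param w Phase-locking mixture levels in [0, 1] (vectorized).
#' @param n_trials Trial count of the dataset being emulated.
#' @param signal_amp_uV Amplitude of the band-limited component *after*
#'   average re-referencing.
#' @param noise_sd_uV Additive noise SD after average re-referencing.
#' @param freq_hz Sinusoid frequency.
#' @param band_hz Analysis band averaged over (closed).
#' @param freqs_hz Analysis frequency grid.
#' @param fs Sampling rate.
#' @param window_ms Morlet window.
#' @param n_channels_avg Number of analysis channels averaged (independent
#'   noise, shared signal).
#' @param n_rep Monte-Carlo replicates.
#' @param phase_diffusion Brownian phase-walk rate of the nonlocked
#'   component, rad^2/s (see [gen_eeg_epochs()]).
#' @param locked_scale,random_scale Amplitude scale factors applied to the
#'   beat-locked and nonlocked components respectively (e.g. the average-
#'   reference attenuation of a shared source vs per-channel sources).
#' @return Numeric vector: expected measured band-averaged ITC for each `w`.
#' @export
itc_response <- function(w, n_trials, signal_amp_uV, noise_sd_uV,
                         freq_hz, band_hz = c(8, 14),
                         freqs_hz = seq(6, 48, by = 1), fs = 1000,
                         window_ms = 500, n_channels_avg = 3, n_rep = 240,
                         phase_diffusion = 5, locked_scale = 1, random_scale = 1) {
  bins <- freqs_hz[freqs_hz >= band_hz[1] - 1e-9 & freqs_hz <= band_hz[2] + 1e-9]
  wl <- morlet_wavelets(bins, fs, window_ms)
  m <- (-wl$half_len:wl$half_len) / fs
  # complex gain of each bin's wavelet to a unit-amplitude sinusoid at freq_hz
  # (positive-frequency term of sin; negative-frequency leakage is negligible)
  gain <- vapply(seq_along(bins), function(b) {
    Mod(sum(Conj(wl$wavelets[, b]) * exp(2i * pi * freq_hz * m)) / (2i))
  }, numeric(1))
  A <- signal_amp_uV * gain                      # per-bin signal magnitude
  sig_n <- noise_sd_uV                           # unit-energy wavelets: noise sd per bin
  nb <- length(bins); nc <- n_channels_avg
  # one shared nonlocked source: all analysis channels see the same draw
  nr <- n_trials * n_rep
  ncol_tot <- n_rep * nb * nc
  bin_of_col <- rep(rep(seq_len(nb), each = nc), times = n_rep)
  rep_of_col <- rep(seq_len(n_rep), each = nb * nc)
  xi_col <- rep_of_col
  # coarse-grained (10 ms) phase walk across the wavelet support; the walk
  # multiplies the nonlocked component by a decoherence factor xi with
  # |xi| <= 1 (energy spread outside the wavelet's phase-coherent passband)
  wstep_s <- 0.010
  lags <- seq(-window_ms / 2, window_ms / 2, by = wstep_s * 1000)
  env10 <- exp(-(lags / 1000)^2 / (2 * wl$sigma_t_s^2))
  env10 <- env10 / sum(env10)
  nw <- length(lags)
  Ltri <- matrix(0, nw, nw); Ltri[lower.tri(Ltri, diag = TRUE)] <- 1
  with_preserved_seed(.CAL_SEED, {
    vapply(w, function(wv) {
      theta <- stats::runif(nr, 0, 2 * pi)
      xi <- if (phase_diffusion > 0) {
        B <- Ltri %*% matrix(stats::rnorm(nw * nr, 0, sqrt(phase_diffusion * wstep_s)), nw, nr)
        as.vector(env10 %*% exp(1i * B))
      } else rep(1 + 0i, nr)
      XI <- matrix(xi * exp(1i * theta), n_trials, n_rep)  # trial x rep
      M <- locked_scale * wv * rep(A[bin_of_col], each = n_trials) +
        random_scale * (1 - wv) * XI[, xi_col, drop = FALSE] *
          rep(A[bin_of_col], each = n_trials)
      M <- M + matrix(complex(real = stats::rnorm(n_trials * ncol_tot, 0, sig_n / sqrt(2)),
                              imaginary = stats::rnorm(n_trials * ncol_tot, 0, sig_n / sqrt(2))),
                      n_trials, ncol_tot)
      itc_col <- Mod(colMeans(M / Mod(M)))
      mean(itc_col)                              # mean over bins, channels, reps
    }, numeric(1))
  })
}

#' Tabulate and invert the target-ITC to mixing-level mapping
#'
#' Evaluates [itc_response()] on a grid of mixing levels and returns a
#' monotone interpolator from target measured ITC to `w`. Targets below the
#' finite-n ITC floor (unreachable by construction) are clamped to `w = 0`;
#' targets above the fully locked response are clamped to `w = 1`.
#'
#' @inheritParams itc_response
#' @param w_grid Grid of mixing levels.
#' @return A function `target -> w`, with the tabulated response attached as
#'   the `"table"` attribute.
#' @export
calibrate_itc <- function(n_trials, signal_amp_uV, noise_sd_uV, freq_hz,
                          band_hz = c(8, 14), freqs_hz = seq(6, 48, by = 1),
                          fs = 1000, window_ms = 500, n_channels_avg = 3,
                          n_rep = 240, w_grid = seq(0, 1, by = 0.05),
                          phase_diffusion = 5, locked_scale = 1, random_scale = 1) {
  key <- paste(signif(c(n_trials, signal_amp_uV, noise_sd_uV, freq_hz, band_hz,
                        range(freqs_hz), length(freqs_hz), fs, window_ms,
                        n_channels_avg, n_rep, w_grid, phase_diffusion,
                        locked_scale, random_scale), 10),
               collapse = "|")
  if (!is.null(.cal_cache[[key]])) {
    resp <- .cal_cache[[key]]
  } else {
    resp <- itc_response(w_grid, n_trials, signal_amp_uV, noise_sd_uV, freq_hz,
                         band_hz, freqs_hz, fs, window_ms, n_channels_avg, n_rep,
                         phase_diffusion, locked_scale, random_scale)
    .cal_cache[[key]] <- resp
  }
  resp_mono <- cummax(resp)    # enforce monotonicity against MC jitter
  f <- function(target) {
    vapply(target, function(tg) {
      if (tg <= resp_mono[1]) return(0)
      if (tg >= resp_mono[length(resp_mono)]) return(1)
      stats::approx(resp_mono, w_grid, xout = tg, ties = "ordered")$y
    }, numeric(1))
  }
  attr(f, "table") <- data.frame(w = w_grid, itc = resp)
  f
}

# Default synthetic montage: mu/beta source restricted to the left motor
# channels; the remaining channels carry only background noise, so average
# re-referencing attenuates the source by (1 - 3/n_channels) instead of
# cancelling it.
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "Fz", "F4", "C5", "C3", "C1", "Cz", "C4",
    "P3", "Pz", "P4", "O1", "O2", "T7")
}

motor_channels <- function() c("C5", "C3", "C1")

# Monte-Carlo expectation of the *detected* trough/peak band ITC for given
# mixing levels: simulates, at the phasor level, the band/channel-averaged
# ITC curve over both search windows (per-trial random phases frozen across
# the epoch, exactly as the generator's mixture prescribes; additive noise
# correlated over time with the wavelet-envelope autocorrelation), then
# takes the min over the trough window and the max over the peak window,
# mirroring the extremum search of the feature extractor.
itc_detect_response <- function(w_t, w_p, params, fs, A, sig_n,
                                bins_hz = seq(8, 14),
                                trough_window = c(-222, -99), peak_window = c(0, 101),
                                step_ms = 10, window_ms = 500, n_channels_avg = 3,
                                n_rep = 100, locked_scale = 1, random_scale = 1) {
  t_tr <- seq(ceiling(trough_window[1] / step_ms) * step_ms, trough_window[2], by = step_ms)
  t_pk <- seq(ceiling(peak_window[1] / step_ms) * step_ms, peak_window[2], by = step_ms)
  t_all <- c(t_tr, t_pk)
  nt <- length(t_all)
  wl <- morlet_wavelets(params$alpha_freq_hz, fs, window_ms)
  env <- exp(-(((-wl$half_len:wl$half_len) / fs)^2) / (2 * wl$sigma_t_s^2))
  env <- env / sum(env)
  w_eff <- vapply(t_all, function(tt) {
    t_need <- tt + (-wl$half_len:wl$half_len) / fs * 1000
    sum(env * mixing_profile(t_need, params$trough_time_ms, params$peak_time_ms, w_t, w_p))
  }, numeric(1))
  # temporal correlation of the noise coefficients = envelope autocorrelation
  env_u <- env / sqrt(sum(env^2))
  acf_env <- function(lag_ms) {
    s <- round(abs(lag_ms) / 1000 * fs)
    if (s >= length(env_u)) return(0)
    sum(env_u[1:(length(env_u) - s)] * env_u[(1 + s):length(env_u)])
  }
  C <- outer(t_all, t_all, function(a, b) vapply(a - b, acf_env, numeric(1)))
  # cross-bin noise correlation from the spectral overlap of the fixed-width
  # wavelets (white noise through overlapping filters); magnitudes only --
  # the relative phases do not survive the band average of ITC maps
  wlb <- morlet_wavelets(bins_hz, fs, window_ms)
  G <- abs(Conj(t(wlb$wavelets)) %*% wlb$wavelets)
  Lbt <- t(chol(kronecker(G, C) + diag(1e-8, nrow(G) * nt)))
  # nonlocked-component time courses on a coarse 10 ms walk grid: shared
  # across bins and channels, decorrelating over time via the phase walk
  g <- seq(min(t_all) - window_ms / 2, max(t_all) + window_ms / 2, by = step_ms)
  ng <- length(g)
  one_minus_w <- 1 - mixing_profile(g, params$trough_time_ms, params$peak_time_ms, w_t, w_p)
  U <- vapply(seq_len(nt), function(j) {
    e <- exp(-((g - t_all[j]) / 1000)^2 / (2 * wl$sigma_t_s^2))
    e[abs(g - t_all[j]) > window_ms / 2 + 1e-9] <- 0
    e * one_minus_w / sum(e)
  }, numeric(ng))
  D <- params$phase_diffusion
  n <- params$n_trials
  nb <- length(A); nc <- n_channels_avg
  nr <- n * n_rep
  Ltri <- matrix(0, ng, ng); Ltri[lower.tri(Ltri, diag = TRUE)] <- 1
  with_preserved_seed(.CAL_SEED + 1L, {
    # one shared nonlocked time course per trial
    theta <- stats::runif(nr, 0, 2 * pi)
    E <- if (D > 0) {
      B <- Ltri %*% matrix(stats::rnorm(ng * nr, 0, sqrt(D * step_ms / 1000)), ng, nr)
      exp(1i * (B + rep(theta, each = ng)))
    } else {
      matrix(exp(1i * theta), ng, nr, byrow = TRUE)
    }
    random_term <- t(E) %*% U                        # (trial,rep) x time
    acc <- matrix(0, n_rep, nt)
    for (cc in seq_len(nc)) {
      # one correlated noise field per channel across all (bin, time) pairs
      eta_all <- (matrix(complex(real = stats::rnorm(nr * nb * nt, 0, 1 / sqrt(2)),
                                 imaginary = stats::rnorm(nr * nb * nt, 0, 1 / sqrt(2))),
                         nr, nb * nt) %*% t(Lbt)) * sig_n
      for (b in seq_len(nb)) {
        eta <- eta_all[, (b - 1L) * nt + seq_len(nt), drop = FALSE]
        M <- A[b] * (locked_scale * rep(1, nr) %o% w_eff +
                     random_scale * random_term) + eta
        U2 <- M / Mod(M)
        # per-rep resultant: average unit phasors within each rep's trials
        for (j in seq_len(nt)) {
          acc[, j] <- acc[, j] + Mod(colMeans(matrix(U2[, j], n, n_rep)))
        }
      }
    }
    acc <- acc / (nb * nc)
    i_tr <- seq_along(t_tr); i_pk <- length(t_tr) + seq_along(t_pk)
    c(trough = mean(apply(acc[, i_tr, drop = FALSE], 1L, min)),
      peak = mean(apply(acc[, i_pk, drop = FALSE], 1L, max)),
      trough_time = mean(t_tr[apply(acc[, i_tr, drop = FALSE], 1L, which.min)]),
      peak_time = mean(t_pk[apply(acc[, i_pk, drop = FALSE], 1L, which.max)]))
  })
}

# Solve for the generator's (w_trough, w_peak) such that the *measured*
# ITC at the two extrema equals the targets. Accounts for (a) the finite-n /
# noise / band-dilution response via calibrate_itc, (b) the smoothing of the
# mixing profile by the wavelet envelope (linear in the knot levels,
# inverted by a clamp-aware 2x2 solve), and (c) the min/max selection of the
# extremum search, corrected by fixed-point iterations against
# itc_detect_response. Targets below the finite-n detection floor saturate
# at w = 0.
solve_mixing_levels <- function(params, time_ms, fs, n_channels,
                                freqs_hz = seq(6, 48, by = 1), window_ms = 500) {
  skey <- paste("solve", paste(signif(c(params$trough_time_ms, params$peak_time_ms,
                                        params$trough_itc, params$peak_itc,
                                        params$alpha_freq_hz, params$beta_itc,
                                        params$beta_freq_hz, params$n_trials,
                                        params$noise_sd_uV, params$alpha_amp_uV,
                                        params$beta_amp_uV, params$phase_diffusion,
                                        fs, n_channels, range(freqs_hz),
                                        length(freqs_hz), window_ms), 10),
                               collapse = "|"))
  if (!is.null(.cal_cache[[skey]])) return(.cal_cache[[skey]])
  # average-reference attenuation: the mu source (locked and nonlocked
  # parts alike) is shared by the three motor channels, so subtracting the
  # channel mean removes 3/C of it
  n_src <- length(motor_channels())
  s_lock <- 1 - n_src / n_channels
  s_rand <- s_lock
  noise_scale <- sqrt(1 - 1 / n_channels)
  cal <- calibrate_itc(params$n_trials, params$alpha_amp_uV,
                       params$noise_sd_uV * noise_scale, params$alpha_freq_hz,
                       band_hz = c(8, 14), freqs_hz = freqs_hz, fs = fs,
                       window_ms = window_ms, phase_diffusion = params$phase_diffusion,
                       n_rep = 120, locked_scale = s_lock, random_scale = s_rand)
  # envelope-smoothing matrix: w_eff(extremum) as a linear map of (w_t, w_p)
  wl <- morlet_wavelets(params$alpha_freq_hz, fs, window_ms)
  env <- exp(-(((-wl$half_len:wl$half_len) / fs)^2) / (2 * wl$sigma_t_s^2))
  env <- env / sum(env)
  smooth_at <- function(w_t, w_p, at_ms) {
    t_need <- at_ms + (-wl$half_len:wl$half_len) / fs * 1000
    sum(env * mixing_profile(t_need, params$trough_time_ms, params$peak_time_ms, w_t, w_p))
  }
  a11 <- smooth_at(1, 0, params$trough_time_ms); a12 <- smooth_at(0, 1, params$trough_time_ms)
  a21 <- smooth_at(1, 0, params$peak_time_ms);   a22 <- smooth_at(0, 1, params$peak_time_ms)
  solve2 <- function(e_t, e_p) {
    sol <- solve(matrix(c(a11, a21, a12, a22), 2L), c(e_t, e_p))
    # clamp-aware: if a level pins at a bound, re-solve the other one exactly
    # so the unpinned extremum still hits its target effective mixing
    w_t <- sol[1]; w_p <- sol[2]
    if (w_t < 0 || w_t > 1) {
      w_t <- min(max(w_t, 0), 1)
      w_p <- (e_p - a21 * w_t) / a22
    } else if (w_p < 0 || w_p > 1) {
      w_p <- min(max(w_p, 0), 1)
      w_t <- (e_t - a12 * w_p) / a11
    }
    c(min(max(w_t, 0), 1), min(max(w_p, 0), 1))
  }
  e_t <- cal(params$trough_itc)
  e_p <- cal(params$peak_itc)
  wtp <- solve2(e_t, e_p)
  knots <- c(params$trough_time_ms, params$peak_time_ms)
  target_times <- knots
  # per-bin signal magnitudes and noise SD seen by the alpha-band analysis,
  # for the selection-aware correction
  bins <- freqs_hz[freqs_hz >= 8 - 1e-9 & freqs_hz <= 14 + 1e-9]
  wlb <- morlet_wavelets(bins, fs, window_ms)
  mvec <- (-wlb$half_len:wlb$half_len) / fs
  gain <- vapply(seq_along(bins), function(b) {
    Mod(sum(Conj(wlb$wavelets[, b]) * exp(2i * pi * params$alpha_freq_hz * mvec)) / (2i))
  }, numeric(1))
  A <- params$alpha_amp_uV * gain
  sig_n <- params$noise_sd_uV * noise_scale
  # fixed-point correction: adjust the ITC targets so the *detected*
  # (min/max-selected) trough and peak match the requested targets
  adj_t <- params$trough_itc; adj_p <- params$peak_itc
  p2 <- params
  for (it in 1:2) {
    p2$trough_time_ms <- knots[1]; p2$peak_time_ms <- knots[2]
    det <- itc_detect_response(wtp[1], wtp[2], p2, fs, A, sig_n, bins_hz = bins,
                               locked_scale = s_lock, random_scale = s_rand)
    if (abs(wtp[2] - wtp[1]) > 0.01) {
      # aim the knots so the *expected detected* extremum times land on the
      # targets; only meaningful when the profile has contrast, and bounded
      # so flat profiles (whose extremum times are unidentifiable, and
      # whose detected times sit mid-window regardless) cannot drift
      knots <- knots + 0.8 * (target_times -
                                c(det[["trough_time"]], det[["peak_time"]]))
      knots <- pmin(pmax(knots, target_times - 50), target_times + 50)
      if (knots[2] - knots[1] <= 10) knots[2] <- knots[1] + 10
    }
    adj_t <- adj_t + (params$trough_itc - det[["trough"]])
    adj_p <- adj_p + (params$peak_itc - det[["peak"]])
    e_t <- cal(min(max(adj_t, 0), 1))
    e_p <- cal(min(max(adj_p, 0), 1))
    wtp <- solve2(e_t, e_p)
  }
  w_t <- wtp[1]; w_p <- wtp[2]
  # beta: constant profile, so w_eff = w directly
  cal_b <- calibrate_itc(params$n_trials, params$beta_amp_uV,
                         params$noise_sd_uV * noise_scale, params$beta_freq_hz,
                         band_hz = c(20, 26), freqs_hz = freqs_hz, fs = fs,
                         window_ms = window_ms, phase_diffusion = params$phase_diffusion,
                         n_rep = 120, locked_scale = s_lock, random_scale = s_rand)
  out <- list(w_trough = w_t, w_peak = w_p, w_beta = cal_b(params$beta_itc),
              e_trough = e_t, e_peak = e_p,
              knot_trough_ms = knots[1], knot_peak_ms = knots[2])
  .cal_cache[[skey]] <- out
  out
}

#' Generate synthetic beat-locked EEG epochs
#'
#' Emulates the statistical structure the beat-locked analysis assumes: on
#' the motor channels (C5, C3, C1) each trial carries an alpha (mu) component
#' that is a smooth mixture of a beat-locked sinusoid and a trial-random-phase
#' sinusoid,
#' `s_k(t) = w(t) sin(2 pi f t + phi0) + (1 - w(t)) sin(2 pi f t + theta_k)`,
#' with the periodic raised-cosine mixing profile `w(t)` at its minimum at
#' the participant's trough time and maximum at the peak time in every beat
#' cycle, plus an analogous beta component with constant mixing, plus
#' additive Gaussian noise with identical statistics on all channels. The
#' nonlocked components' phases follow a slow Brownian walk
#' (`phase_diffusion`), giving them the finite coherence time of spontaneous
#' sensorimotor rhythms instead of a trial-frozen phase. The mixing levels
#' are obtained from the target ITC values through the finite-n calibration
#' oracle ([calibrate_itc()]) with a selection-aware correction
#' (`itc_detect_response`), so the *detected* trough/peak band-averaged ITC
#' matches the targets in expectation.
#'
#' @param params An [eeg_params()] object.
#' @param schedule Optional [make_beat_schedule()]; when given, at most the
#'   number of strong beats many trials are generated and beat bookkeeping is
#'   attached.
#' @param fs Sampling rate in Hz (>= 250).
#' @param channels Channel names; must include C5, C3, C1.
#' @param window_ms Epoch window (must contain [-500, 500] so the baseline
#'   window fits).
#' @param noise_kind `"white"` (default) or `"pink"` (1/f-filtered) noise.
#' @return An [eeg_epochs()] object with a `ground_truth` attribute (the
#'   params and resolved mixing levels). Downstream analysis code must not
#'   read the attribute.
#' @export
gen_eeg_epochs <- function(params, schedule = NULL, fs = 1000,
                           channels = default_montage(),
                           window_ms = c(-800, 800),
                           noise_kind = c("white", "pink")) {
  stopifnot(inherits(params, "participant_eeg_params"))
  noise_kind <- match.arg(noise_kind)
  if (fs < 250) stop("fs must be at least 250 Hz")
  if (window_ms[1] > -500 || window_ms[2] < 500) {
    stop("epoch window must contain [-500, 500] ms (baseline window)")
  }
  if (!all(motor_channels() %in% channels)) {
    stop("channel list must include the motor channels C5, C3, C1")
  }
  n_trials <- params$n_trials
  if (!is.null(schedule)) n_trials <- min(n_trials, length(schedule$strong_beat_times_s))
  time_ms <- seq(round(window_ms[1] * fs / 1000), round(window_ms[2] * fs / 1000)) / fs * 1000
  ns <- length(time_ms)
  nc <- length(channels)
  lv <- solve_mixing_levels(params, time_ms, fs, nc)
  w_a <- mixing_profile(time_ms, lv$knot_trough_ms, lv$knot_peak_ms,
                        lv$w_trough, lv$w_peak)
  t_s <- time_ms / 1000
  locked_a <- sin(2 * pi * params$alpha_freq_hz * t_s)
  locked_b <- sin(2 * pi * params$beta_freq_hz * t_s)
  mi <- match(motor_channels(), channels)
  dat <- array(0, c(nc, ns, n_trials))
  sd_step <- sqrt(params$phase_diffusion / fs)
  with_preserved_seed(params$seed, {
    # the mu/beta source is one shared generator under C5/C3/C1: the locked
    # and nonlocked parts appear identically on all three motor channels
    theta_a <- stats::runif(n_trials, 0, 2 * pi)
    theta_b <- stats::runif(n_trials, 0, 2 * pi)
    for (k in seq_len(n_trials)) {
      walk_a <- cumsum(stats::rnorm(ns, 0, sd_step))
      walk_b <- cumsum(stats::rnorm(ns, 0, sd_step))
      sa <- params$alpha_amp_uV *
        (w_a * locked_a +
         (1 - w_a) * sin(2 * pi * params$alpha_freq_hz * t_s + theta_a[k] + walk_a))
      sb <- params$beta_amp_uV *
        (lv$w_beta * locked_b +
         (1 - lv$w_beta) * sin(2 * pi * params$beta_freq_hz * t_s + theta_b[k] + walk_b))
      trial <- matrix(0, nc, ns)
      trial[mi, ] <- rep(sa + sb, each = length(mi))
      noise <- matrix(stats::rnorm(nc * ns, 0, params$noise_sd_uV), nc, ns)
      if (noise_kind == "pink") noise <- t(apply(noise, 1L, pink_filter, fs = fs))
      dat[, , k] <- trial + noise
    }
  })
  out <- eeg_epochs(dat, fs, time_ms, channels)
  attr(out, "ground_truth") <- c(params[setdiff(names(params), "")],
                                 lv[c("w_trough", "w_peak", "w_beta")])
  out
}

# 1/f amplitude shaping of a white-noise vector (unit-variance preserved).
pink_filter <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))         # avoid division by zero at DC
  f <- pmin(f, n - f + 1)           # two-sided frequency index
  shape <- 1 / sqrt(f)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y * stats::sd(x) / stats::sd(y)
}
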