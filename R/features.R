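#' Locate the pre-beat ITC trough
#'
#' Finds the lowest local minimum of a band-ITC time series inside the
#' closed search window (default [-222, -99] ms, the pre-beat regime in
#' which sensorimotor alpha desynchronizes). A sample is a local minimum if
#' it is lower than both neighbors; a window-boundary sample counts when it
#' is lower than its single in-window neighbor, so the result always equals
#' the in-window global minimum. A plateau of equal values flanked by higher
#' neighbors counts once, at its center sample. Ties between equal-valued
#' minima are broken toward the earlier time. On a constant (single-run)
#' series the search falls back to the earliest window sample.
#'
#' @param series A `band_series` (channel-averaged) or numeric vector.
#' @param times_ms Sample times in ms (taken from the series attribute if
#'   absent).
#' @param window_ms Closed search window in ms.
#' @return List with `time_ms`, `value`, and `interior` (TRUE if an interior
#'   local extremum was found, FALSE if the fallback was used).
#' @export
find_trough <- function(series, times_ms = attr(series, "times_ms"),
                        window_ms = c(-222, -99)) {
  find_extremum(as.numeric(series), times_ms, window_ms, maximum = FALSE)
}

#' Locate the post-beat ITC peak
#'
#' Mirror image of [find_trough()]: the highest interior local maximum in
#' the closed window (default [0, 101] ms), with the same plateau, tie, and
#' global-extremum fallback rules.
#'
#' @inheritParams find_trough
#' @export
find_peak <- function(series, times_ms = attr(series, "times_ms"),
                      window_ms = c(0, 101)) {
  find_extremum(as.numeric(series), times_ms, window_ms, maximum = TRUE)
}

find_extremum <- function(x, times_ms, window_ms, maximum = FALSE) {
  if (is.null(times_ms) || length(times_ms) != length(x)) {
    stop("'times_ms' missing or mismatched")
  }
  sel <- which(times_ms >= window_ms[1] - 1e-9 & times_ms <= window_ms[2] + 1e-9)
  if (length(sel) == 0L) stop("series does not cover the search window")
  v <- x[sel]
  if (maximum) v <- -v
  tw <- times_ms[sel]
  n <- length(v)
  cand_idx <- integer(0)
  if (n >= 2L) {
    # collapse runs of equal values; an interior run is a local min if both
    # flanking runs are higher (plateau representative = center sample); a
    # window-boundary run qualifies when it dips below its single neighbor,
    # so the lowest candidate always equals the in-window global minimum
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nr_ <- length(r$values)
    cand_int <- logical(0)
    for (j in seq_len(nr_)) {
      lower_left <- j == 1L || r$values[j] < r$values[j - 1L]
      lower_right <- j == nr_ || r$values[j] < r$values[j + 1L]
      if (nr_ > 1L && lower_left && lower_right) {
        cand_idx <- c(cand_idx, floor((starts[j] + ends[j]) / 2))
        cand_int <- c(cand_int, j > 1L && j < nr_)
      }
    }
  }
  if (length(cand_idx) > 0L) {
    k <- which.min(v[cand_idx])                         # earliest wins ties via which.min
    best <- cand_idx[k]
    interior <- cand_int[k]
  } else {
    best <- which.min(v)
    interior <- FALSE
  }
  list(time_ms = tw[best], value = x[sel][best], interior = interior)
}

#' Trough-to-peak ITC slope
#'
#' The rise from the ITC trough to the ITC peak, expressed per second:
#' `(peak_itc - trough_itc) / ((peak_time_ms - trough_time_ms)/1000)`. The
#' bare rise (difference in ITC units) is returned alongside, and
#' `slope_positive` records whether the peak ITC exceeds the trough ITC.
#'
#' @param trough,peak Lists with `time_ms` and `value` (as returned by
#'   [find_trough()] / [find_peak()]).
#' @return List with `slope_per_s`, `rise`, `slope_positive`.
#' @export
itc_slope <- function(trough, peak) {
  if (peak$time_ms <= trough$time_ms) stop("peak time must exceed trough time")
  rise <- peak$value - trough$value
  list(slope_per_s = rise / ((peak$time_ms - trough$time_ms) / 1000),
       rise = rise, slope_positive = rise > 0)
}

#' Extract the trough/peak/slope features from an alpha-ITC series
#'
#' Convenience wrapper running [find_trough()], [find_peak()] and
#' [itc_slope()] with the standard windows.
#'
#' @param series Channel-averaged alpha-band ITC `band_series`.
#' @param trough_window_ms,peak_window_ms Search windows.
#' @return One-row data frame: `trough_time_ms`, `trough_itc`,
#'   `peak_time_ms`, `peak_itc`, `slope`, `rise`, `slope_positive`.
#' @export
itc_features <- function(series, trough_window_ms = c(-222, -99),
                         peak_window_ms = c(0, 101)) {
  tr <- find_trough(series, window_ms = trough_window_ms)
  pk <- find_peak(series, window_ms = peak_window_ms)
  sl <- itc_slope(tr, pk)
  data.frame(trough_time_ms = tr$time_ms, trough_itc = tr$value,
             peak_time_ms = pk$time_ms, peak_itc = pk$value,
             slope = sl$slope_per_s, rise = sl$rise,
             slope_positive = sl$slope_positive)
}

#' Paired-sample t test (closed form)
#'
#' Two-sided paired t test on per-participant values: with d = x - y,
#' t = mean(d) / (sd(d)/sqrt(n)), df = n - 1, and a 95% CI for mean(d) from
#' the t distribution. Zero-variance differences are an error (the statistic
#' is undefined), not a silent 0/0.
#'
#' @param x,y Equal-length numeric vectors (n >= 2), paired by position.
#' @return A `group_stats` data frame row: `n`, `mean`, `sd`, `ci95_low`,
#'   `ci95_high`, `t_stat`, `df`, `p_value`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stop("zero-variance differences: paired t statistic undefined")
  m <- mean(d)
  se <- s / sqrt(n)
  t_stat <- m / se
  df <- n - 1L
  tc <- stats::qt(0.975, df)
  data.frame(n = n, mean = m, sd = s,
             ci95_low = m - tc * se, ci95_high = m + tc * se,
             t_stat = t_stat, df = df,
             p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Independent-samples t test (pooled variance, closed form)
#'
#' Two-sided two-sample t test with pooled variance and
#' df = n1 + n2 - 2, plus a 95% CI for the mean difference.
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @return A `group_stats`-style data frame row (mean is the difference of
#'   group means).
#' @export
independent_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance: t statistic undefined")
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  m <- mean(x) - mean(y)
  df <- n1 + n2 - 2L
  tc <- stats::qt(0.975, df)
  data.frame(n = n1 + n2, mean = m, sd = sqrt(sp2),
             ci95_low = m - tc * se, ci95_high = m + tc * se,
             t_stat = m / se, df = df,
             p_value = 2 * stats::pt(-abs(m / se), df))
}

#' Simple linear regression (ordinary least squares, closed form)
#'
#' Fits y = a + b x by least squares and reports the slope, intercept, R
#' squared, the overall F statistic with (1, n - 2) degrees of freedom, and
#' its two-sided p value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3 for inference).
#' @return Data frame row: `slope`, `intercept`, `r_squared`, `f_stat`,
#'   `df1`, `df2`, `p_value`.
#' @export
simple_linreg <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant predictor")
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  fit <- a + b * x
  ss_res <- sum((y - fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  df2 <- n - 2L
  f_stat <- if (ss_res == 0) Inf else (ss_tot - ss_res) / (ss_res / df2)
  data.frame(slope = b, intercept = a, r_squared = r2, f_stat = f_stat,
             df1 = 1L, df2 = df2,
             p_value = stats::pf(f_stat, 1, df2, lower.tail = FALSE))
}

#' Fraction of participants with a positive ITC slope
#'
#' @param features Data frame with a logical `slope_positive` column (one
#'   row per participant), or a logical vector.
#' @return Fraction in [0, 1].
#' @export
positive_slope_fraction <- function(features) {
  v <- if (is.data.frame(features)) features$slope_positive else features
  if (length(v) == 0L) stop("empty feature list")
  mean(v)
}
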