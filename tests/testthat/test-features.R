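mk_series <- function(vals, times) structure(vals, times_ms = times, class = "band_series")

test_that("trough/peak finders locate unique interior extrema", {
  tms <- seq(-400, 200, by = 2)
  dip <- 0.1 - 0.05 * exp(-(tms + 150)^2 / (2 * 30^2))
  tr <- find_trough(mk_series(dip, tms))
  expect_equal(tr$time_ms, -150)
  expect_true(tr$interior)
  bump <- 0.1 + 0.05 * exp(-(tms - 46)^2 / (2 * 20^2))
  pk <- find_peak(mk_series(bump, tms))
  expect_equal(pk$time_ms, 46)
  expect_equal(pk$value, max(bump[tms >= 0 & tms <= 101]))
})

test_that("monotone and flat series fall back to the window extremum", {
  tms <- seq(-300, 150, by = 3)
  inc <- seq_along(tms) / 100
  tr <- find_trough(mk_series(inc, tms))
  expect_false(tr$interior)
  expect_equal(tr$time_ms, tms[tms >= -222][1])    # left endpoint of the window
  flat <- mk_series(rep(0.3, length(tms)), tms)
  pk <- find_peak(flat)
  expect_false(pk$interior)
  expect_equal(pk$value, 0.3)
  expect_equal(pk$time_ms, 0)                      # earliest on ties
})

test_that("plateaus count once at their center sample", {
  tms <- seq(-220, -100, by = 10)
  v <- c(5, 4, 3, 3, 3, 4, 5, 4, 5, 6, 7, 8, 9)
  tr <- find_trough(mk_series(v, tms), window_ms = c(-222, -99))
  expect_equal(tr$time_ms, -190)                   # center of the 3,3,3 run
  expect_equal(tr$value, 3)
})

test_that("extremum finders match exhaustive window scans on random series", {
  set.seed(100)
  tms <- seq(-400, 300, by = 10)
  for (i in 1:1000) {
    v <- runif(length(tms))
    tr <- find_trough(mk_series(v, tms))
    pk <- find_peak(mk_series(v, tms))
    in_tr <- tms >= -222 & tms <= -99
    in_pk <- tms >= 0 & tms <= 101
    expect_identical(tr$value, min(v[in_tr]))
    expect_identical(pk$value, max(v[in_pk]))
  }
})

test_that("slope is the rise per second with the sign stored separately", {
  tr <- list(time_ms = -156, value = 0.06)
  pk <- list(time_ms = 46, value = 0.11)
  sl <- itc_slope(tr, pk)
  expect_equal(sl$slope_per_s, 0.05 / 0.202, tolerance = 1e-12)   # ~0.2475 /s
  expect_true(sl$slope_positive)
  expect_equal(itc_slope(list(time_ms = -100, value = 0.2),
                         list(time_ms = 50, value = 0.2))$slope_per_s, 0)
  inv <- itc_slope(list(time_ms = -150, value = 0.12), list(time_ms = 40, value = 0.07))
  expect_lt(inv$slope_per_s, 0)
  expect_false(inv$slope_positive)
  expect_error(itc_slope(pk, tr), "exceed")
})

test_that("paired t matches its closed form and the reference implementation", {
  d <- c(0.1, 0.2, 0.3)
  r <- paired_t(d, rep(0, 3))
  expect_equal(r$t_stat, 3.4641016, tolerance = 1e-6)
  expect_equal(r$df, 2L)

  expect_error(paired_t(1:5, 1:5), "zero-variance")
  anti <- c(-1, 1, -2, 2)
  expect_equal(paired_t(anti, rep(0, 4))$t_stat, 0)

  set.seed(8)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_lt(abs(mine$t_stat - ref$statistic), 1e-10)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-10)
    expect_lt(max(abs(c(mine$ci95_low, mine$ci95_high) - ref$conf.int)), 1e-10)
  }
})

test_that("independent t and OLS match the reference implementations", {
  set.seed(9)
  for (i in 1:25) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(sample(3:30, 1), 0.3)
    mine <- independent_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_lt(abs(mine$t_stat - ref$statistic), 1e-10)
    expect_lt(abs(mine$p_value - ref$p.value), 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
  g1 <- c(1, 2, 3); g2 <- c(2, 1, 3)
  expect_equal(independent_t(g1, g2)$t_stat, 0)

  for (i in 1:25) {
    n <- sample(4:50, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    mine <- simple_linreg(x, y)
    ref <- summary(lm(y ~ x))
    expect_lt(abs(mine$slope - coef(ref)[2, 1]), 1e-10)
    expect_lt(abs(mine$r_squared - ref$r.squared), 1e-10)
    expect_lt(abs(mine$f_stat - ref$fstatistic[1]) / max(1, ref$fstatistic[1]), 1e-8)
    expect_lt(abs(mine$p_value - pf(ref$fstatistic[1], 1, n - 2, lower.tail = FALSE)), 1e-10)
  }
  exact <- simple_linreg(1:10, 2 * (1:10))
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
})

test_that("positive slope fraction counts correctly and rejects empty input", {
  f <- data.frame(slope_positive = c(rep(TRUE, 26), FALSE))
  expect_equal(positive_slope_fraction(f), 26 / 27)
  expect_equal(round(100 * positive_slope_fraction(f), 2), 96.30)
  expect_equal(positive_slope_fraction(rep(TRUE, 5)), 1)
  expect_error(positive_slope_fraction(logical(0)), "empty")
})
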