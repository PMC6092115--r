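test_that("uniform_ts validates its invariants", {
  expect_error(uniform_ts(1:10, fs = 0), "positive")
  expect_error(uniform_ts(5, fs = 200), "at least 2")
  expect_error(uniform_ts(c(1, NA, 3), fs = 200), "finite")
  x <- uniform_ts(1:5, fs = 10, t0 = 2)
  expect_equal(ts_time(x), 2 + (0:4) / 10)
  expect_equal(ts_duration(x), 0.4)
})

test_that("dual-pass filtering preserves DC and is zero-phase", {
  x <- uniform_ts(rep(5, 400), fs = 200)
  for (ord in c(1, 2, 4)) {
    y <- butter_dual_pass(x, filter_spec(10, ord))
    expect_lt(max(abs(y$values - 5)), 5 * 1e-12)
  }
  # zero lag: a passband sinusoid's cross-correlation peaks at lag 0
  t <- (0:1599) / 200
  s <- uniform_ts(sin(2 * pi * 1 * t), fs = 200)
  y <- butter_dual_pass(s, filter_spec(10, 2))
  lags <- -30:30
  cc <- vapply(lags, function(L) {
    i <- 200:1400
    sum(s$values[i] * y$values[i + L])
  }, numeric(1))
  expect_identical(lags[which.max(cc)], 0L)
})

test_that("dual-pass magnitude at the cutoff is the squared single-pass gain", {
  # analytic single-pass Butterworth gain at f = cutoff is 1/sqrt(2)
  # regardless of order, so the two-pass gain is 1/2
  t <- (0:1599) / 200
  s <- uniform_ts(sin(2 * pi * 10 * t), fs = 200)
  for (ord in c(1, 2, 4)) {
    y <- butter_dual_pass(s, filter_spec(10, ord))
    i <- 400:1200
    fit <- lm(y$values[i] ~ sin(2 * pi * 10 * t[i]) + cos(2 * pi * 10 * t[i]) - 1)
    gain <- sqrt(sum(coef(fit)^2))
    expect_equal(gain, 0.5, tolerance = 0.01)
  }
})

test_that("filtering is linear", {
  set.seed(101)
  fs <- 200
  x <- uniform_ts(rnorm(500), fs)
  y <- uniform_ts(rnorm(500), fs)
  a <- 2.5; b <- -0.7
  spec <- filter_spec(10, 2)
  lhs <- butter_dual_pass(uniform_ts(a * x$values + b * y$values, fs), spec)$values
  rhs <- a * butter_dual_pass(x, spec)$values + b * butter_dual_pass(y, spec)$values
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("filter rejects bad parameters and short series", {
  x <- uniform_ts(rnorm(100), fs = 200)
  expect_error(butter_dual_pass(x, filter_spec(100)), "Nyquist")
  expect_error(butter_dual_pass(x, filter_spec(150)), "Nyquist")
  short <- uniform_ts(rnorm(10), fs = 200)
  expect_error(butter_dual_pass(short, filter_spec(10, 2)), "too short")
})

test_that("baseline_stats matches hand arithmetic and a brute-force oracle", {
  x <- uniform_ts(c(1, 1, 1, 9), fs = 1, t0 = 0)
  bl <- baseline_stats(x, c(0, 3)) # half-open: excludes the 9 at t = 3
  expect_equal(bl$mean, 1)
  expect_equal(bl$sd, 0)
  expect_equal(bl$n, 3L)

  y <- uniform_ts(c(1, 2, 3, 99), fs = 1)
  bl2 <- baseline_stats(y, c(0, 3))
  expect_equal(bl2$mean, 2)
  expect_equal(bl2$sd, 1)

  set.seed(77)
  v <- rnorm(1000)
  z <- uniform_ts(v, fs = 100)
  bl3 <- baseline_stats(z, c(0, 10))
  # independent summation oracle
  m <- sum(v) / 1000
  s <- sqrt(sum((v - m)^2) / 999)
  expect_equal(bl3$mean, m, tolerance = 1e-12)
  expect_equal(bl3$sd, s, tolerance = 1e-12)

  expect_error(baseline_stats(z, c(5, 5)), "t_end > t_start")
  expect_error(baseline_stats(z, c(20, 21)), "fewer than 2")
})

test_that("onset detection finds steps and analytic ramp crossings", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  step <- uniform_ts(ifelse(t >= 5, 1, 0), fs)
  bl <- baseline_stats(step, c(0, 1))
  expect_equal(onset_by_threshold(step, bl, search_from = 1, min_hold = 0), 5.0)

  # noise-free ramp: threshold mean + 2 sd crossed at analytic t*
  base <- rep(c(-0.1, 0.1), 100) # mean 0, known sd
  ramp <- uniform_ts(c(base, pmax(0, 0.8 * (t[-(1:200)] - 2))), fs)
  blr <- baseline_stats(ramp, c(0, 1))
  tstar <- 2 + 2 * blr$sd / 0.8
  got <- onset_by_threshold(ramp, blr, search_from = 1, min_hold = 0.05)
  expect_gte(got, tstar - 1e-9)
  expect_lt(got - tstar, 1.5 / fs) # first sample strictly beyond t*

  flat <- uniform_ts(rep(0, 1000), fs)
  blf <- baseline_stats(flat, c(0, 1))
  expect_true(is.na(onset_by_threshold(flat, blf)))
})

test_that("onset detection is translation-equivariant and min_hold rejects spikes", {
  fs <- 200
  t <- (0:(8 * fs - 1)) / fs
  sig <- ifelse(t >= 4, 2, 0)
  sig[600] <- 5 # single-sample spike at t = 3
  for (dt in c(0, 1.3, -0.6)) {
    x <- uniform_ts(sig, fs, t0 = dt)
    bl <- baseline_stats(x, c(dt, dt + 1))
    on <- onset_by_threshold(x, bl, search_from = dt + 1, min_hold = 0.05)
    expect_equal(on, 4 + dt, tolerance = 1e-9)
  }
})

test_that("rms_displacement matches closed forms and scales linearly", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs
  expect_equal(rms_displacement(uniform_ts(rep(3, 800), fs), c(0, 4), 3), 0)
  expect_equal(rms_displacement(uniform_ts(rep(3, 800), fs), c(0, 4), 1.2), 1.8)
  # sinusoid over whole periods: RMS = A / sqrt(2)
  A <- 2.4
  s <- uniform_ts(7 + A * sin(2 * pi * 2 * t), fs)
  expect_equal(rms_displacement(s, c(0, 2), 7), A / sqrt(2), tolerance = 1e-6)
  # linear scaling about the reference
  s2 <- uniform_ts(7 + 3 * A * sin(2 * pi * 2 * t), fs)
  expect_equal(rms_displacement(s2, c(0, 2), 7),
               3 * rms_displacement(s, c(0, 2), 7), tolerance = 1e-9)
  # order within the interval does not matter
  set.seed(5)
  v <- rnorm(800)
  expect_equal(rms_displacement(uniform_ts(v, fs), c(0, 4), 0),
               rms_displacement(uniform_ts(rev(v), fs), c(0, 4), 0))
  expect_error(rms_displacement(s, c(10, 11), 0), "no samples")
})
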