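test_that("platform profile reproduces the protocol kinematics", {
  p <- gen_platform_profile() # 12 cm, 15 cm/s, 100 cm/s^2 at 200 Hz
  x <- p$values
  fs <- p$fs
  expect_equal(attr(p, "movement_time"), 0.95)
  expect_equal(max(abs(x - x[1])), 12, tolerance = 0.01 * 12)
  v <- (x[-(1:2)] - x[1:(length(x) - 2)]) * fs / 2 # central difference
  expect_equal(max(abs(v)), 15, tolerance = 0.01 * 15)
  a <- diff(x, differences = 2) * fs^2
  expect_equal(max(abs(a)), 100, tolerance = 0.01 * 100)
  # phase structure: ramps of v/a = 0.15 s around a 0.65 s cruise
  expect_equal(sum(abs(abs(v) - 15) < 1e-6) / fs, 0.65, tolerance = 0.02)
})

test_that("feasibility boundary gives a triangular profile; beyond it errors", {
  tri <- gen_platform_profile(amplitude = 2.25, peak_velocity = 15,
                              peak_acceleration = 100)
  expect_equal(attr(tri, "movement_time"), 0.3) # 2 * v/a, zero cruise
  expect_equal(max(abs(tri$values)), 2.25, tolerance = 1e-9)
  expect_error(gen_platform_profile(amplitude = 2.0, peak_velocity = 15,
                                    peak_acceleration = 100), "infeasible")
  expect_error(gen_platform_profile(amplitude = -1), "positive")
})

test_that("generators are pure functions of spec and seed", {
  a <- gen_walk_trial(duration = 20, seed = 42,
                      freeze_episodes = data.frame(t_start = 8, t_end = 12))
  b <- gen_walk_trial(duration = 20, seed = 42,
                      freeze_episodes = data.frame(t_start = 8, t_end = 12))
  expect_identical(a$series$values, b$series$values)
  c <- gen_walk_trial(duration = 20, seed = 43,
                      freeze_episodes = data.frame(t_start = 8, t_end = 12))
  expect_false(identical(a$series$values, c$series$values))

  s1 <- gen_step_trial(seed = 7)
  s2 <- gen_step_trial(seed = 7)
  expect_identical(s1$trial$ml_force$values, s2$trial$ml_force$values)

  p1 <- gen_perturbation_trial(seed = 5)
  p2 <- gen_perturbation_trial(seed = 5)
  expect_identical(p1$trial$plate$My$values, p2$trial$plate$My$values)
  expect_identical(p1$truth$onset, p2$truth$onset)
})

test_that("walk generator validates episodes", {
  expect_error(gen_walk_trial(duration = 20,
                              freeze_episodes = data.frame(t_start = c(5, 8),
                                                           t_end = c(9, 12))),
               "overlap")
  expect_error(gen_walk_trial(duration = 20,
                              freeze_episodes = data.frame(t_start = 5, t_end = 9,
                                                           freeze_freq = 10)),
               "3-8")
  expect_error(gen_walk_trial(duration = 10,
                              freeze_episodes = data.frame(t_start = 1, t_end = 25)),
               "inside the walk interval")
})

test_that("pure locomotion yields no freeze calls; episodes are recovered", {
  clean <- gen_walk_trial(duration = 30, noise_sd = 0, seed = 1)
  r <- detect_fog(clean$series, marks = clean$truth$walk_interval)
  expect_identical(nrow(r$events), 0L)

  g <- gen_walk_trial(duration = 40,
                      freeze_episodes = data.frame(t_start = 16, t_end = 24),
                      seed = 6)
  r2 <- detect_fog(g$series, marks = g$truth$walk_interval)
  expect_identical(nrow(r2$events), 1L)
  expect_lt(abs(r2$total_fog_time - g$truth$total_freeze_time), 1)
})

test_that("freeze-count recovery is exact over a seeded sweep", {
  # episodes >= span long and >= span apart are counted exactly
  for (s in 1:20) {
    g <- gen_walk_trial(duration = 45,
                        freeze_episodes = data.frame(t_start = c(10, 28),
                                                     t_end = c(18, 36)),
                        seed = 200 + s)
    r <- detect_fog(g$series, marks = g$truth$walk_interval)
    expect_identical(nrow(r$events), 2L)
  }
})

test_that("step block writes n trial files that the reader round-trips", {
  dir <- withr::local_tempdir()
  gen_step_block(n = 10, out_dir = dir, seed = 3)
  csvs <- list.files(dir, pattern = "^step_\\d+\\.csv$")
  expect_length(csvs, 10)
  expect_length(list.files(dir, pattern = "_truth\\.json$"), 10)
  tr <- read_step_trial(file.path(dir, csvs[1]))
  expect_s3_class(tr$trial, "step_trial")
  m <- apa_metrics(tr$trial)
  expect_true(m$valid)
})

test_that("zero sway gain reduces the COM to the platform translation", {
  g <- gen_perturbation_trial(sway_gain = 0, noise_sd = 0, seed = 2)
  com <- com_ap(g$trial$markers)
  dev <- (com$values - com$values[1]) - g$platform$values
  expect_lt(max(abs(dev)), 1e-9)
  # and the truth RMS equals the analytic RMS of the profile over the window
  t <- ts_time(g$platform)
  i <- which(t >= g$truth$onset & t < g$truth$onset + 2.5)
  ref <- mean(g$platform$values[t >= g$truth$onset - 1 & t < g$truth$onset])
  expect_equal(g$truth$rms_com_ap,
               sqrt(mean((g$platform$values[i] - ref)^2)), tolerance = 1e-9)
})

test_that("reactive metrics recover the generator truth within 2%", {
  for (s in c(1, 9, 17)) {
    g <- gen_perturbation_trial(seed = s)
    m <- reactive_metrics(g$trial)
    expect_lt(abs(m$rms_com_ap / g$truth$rms_com_ap - 1), 0.02)
    expect_lt(abs(m$rms_cop_ap / g$truth$rms_cop_ap - 1), 0.02)
  }
})

test_that("zero perturbation amplitude yields near-zero metrics", {
  g <- gen_perturbation_trial(amplitude = 1e-9, peak_velocity = 1e-9,
                              peak_acceleration = 1e-9, noise_sd = 0, seed = 3)
  m <- reactive_metrics(g$trial)
  expect_lt(m$rms_com_ap, 1e-6)
  expect_lt(m$rms_cop_ap, 1e-6)
})
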