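const_uts <- function(v, n = 400, fs = 200) uniform_ts(rep(v, n), fs)

test_that("com_ap reduces to the common value for coincident markers", {
  mk <- marker_set(const_uts(12), const_uts(12), const_uts(12),
                   const_uts(12), const_uts(12))
  com <- com_ap(mk)
  expect_equal(com$values, rep(12, 400), tolerance = 1e-12)
  expect_equal(com$units, "cm")
})

test_that("com_ap is translation-equivariant and matches the brute-force oracle", {
  for (s in 1:10) {
    rm <- random_marker_set(seed = 100 + s)
    com <- com_ap(rm$set)
    oracle <- oracle_com_ap(rm$values, winter_model()$segments)
    expect_lt(max(abs(com$values - oracle)) / max(1, max(abs(oracle))), 1e-9)
    shifted <- lapply(rm$values, function(v) v + 3)
    com_s <- com_ap(marker_set(
      meta5 = uniform_ts(shifted$meta5, 200), malleolus = uniform_ts(shifted$malleolus, 200),
      knee = uniform_ts(shifted$knee, 200), trochanter = uniform_ts(shifted$trochanter, 200),
      shoulder = uniform_ts(shifted$shoulder, 200)))
    expect_lt(max(abs(com_s$values - (com$values + 3))), 1e-12 * 100)
  }
})

test_that("com_ap is invariant under proximal/distal relabelling", {
  seg <- winter_model()$segments
  swapped <- seg
  swapped$proximal <- seg$distal
  swapped$distal <- seg$proximal
  swapped$com_fraction <- 1 - seg$com_fraction
  rm <- random_marker_set(seed = 55)
  a <- com_ap(rm$set, anthro_model(seg))$values
  b <- com_ap(rm$set, anthro_model(swapped))$values
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("anthro_model rejects inconsistent segment tables", {
  seg <- winter_model()$segments
  seg$mass_fraction[1] <- 0.1
  expect_error(anthro_model(seg), "sum to")
  mk <- random_marker_set(seed = 2)$set
  bad <- winter_model()
  bad$segments$distal[1] <- "toe"
  expect_error(com_ap(mk, bad), "absent")
})

test_that("cop_ap implements plate statics", {
  n <- 400
  zero <- const_uts(0, n)
  f700 <- const_uts(700, n)
  plate0 <- force_plate_record(zero, zero, f700, zero, zero, zero)
  expect_equal(cop_ap(plate0)$values, rep(0, n))

  # static point load 700 N at ap = +0.10 m => My = -70 N m
  plate1 <- force_plate_record(zero, zero, f700, zero, const_uts(-70, n), zero)
  expect_equal(cop_ap(plate1)$values, rep(10, n), tolerance = 1e-9)

  # origin offsets enter the statics
  fx <- const_uts(35, n)
  plate2 <- force_plate_record(fx, zero, f700, zero, const_uts(-70, n), zero,
                               origin_offset = c(0.02, 0, -0.04))
  want <- (-(-70 + 35 * -0.04) / 700 + 0.02) * 100
  expect_equal(cop_ap(plate2)$values, rep(want, n), tolerance = 1e-9)

  # vertical load below the floor is an error naming the first bad time
  fz_bad <- uniform_ts(c(rep(700, 100), rep(10, 10), rep(700, 290)), 200)
  plate3 <- force_plate_record(zero, zero, fz_bad, zero, zero, zero)
  expect_error(cop_ap(plate3), "0\\.5000")
  expect_error(cop_ap(force_plate_record(zero, zero, const_uts(0, n),
                                         zero, zero, zero)), "Fz")
})

test_that("reactive_metrics: constants give zero, sinusoids give A/sqrt(2)", {
  fs <- 200
  n <- 8 * fs + 1
  t <- (0:(n - 1)) / fs
  mkc <- marker_set(const_uts(12, n), const_uts(12, n), const_uts(12, n),
                    const_uts(12, n), const_uts(12, n))
  platec <- force_plate_record(const_uts(0, n), const_uts(0, n), const_uts(700, n),
                               const_uts(0, n), const_uts(-70, n), const_uts(0, n))
  tr <- perturbation_trial(mkc, platec, perturbation_onset = 2, analysis_window = 2.5)
  m0 <- reactive_metrics(tr)
  expect_equal(m0$rms_com_ap, 0, tolerance = 1e-9)
  expect_equal(m0$rms_cop_ap, 0, tolerance = 1e-9)

  # COM response: 2 cm, 2 Hz damped-free sinusoid about rest; analysis
  # window holds whole periods; compare with numeric integration
  A <- 2; f0 <- 2
  sway <- ifelse(t >= 2, A * sin(2 * pi * f0 * (t - 2)), 0)
  mks <- marker_set(uniform_ts(12 + sway, fs), uniform_ts(12 + sway, fs),
                    uniform_ts(12 + sway, fs), uniform_ts(12 + sway, fs),
                    uniform_ts(12 + sway, fs))
  trs <- perturbation_trial(mks, platec, perturbation_onset = 2, analysis_window = 2.5)
  ms <- reactive_metrics(trs, filter = NULL)
  oracle <- sqrt(stats::integrate(function(u) (A * sin(2 * pi * f0 * u))^2,
                                  0, 2.5, subdivisions = 2000L)$value / 2.5)
  expect_equal(ms$rms_com_ap, oracle, tolerance = 0.02)
  expect_equal(oracle, A / sqrt(2), tolerance = 1e-6)

  expect_error(perturbation_trial(mkc, platec, perturbation_onset = 7.5,
                                  analysis_window = 2.5) |> reactive_metrics(),
               "extends past")
})

test_that("reactive_metrics is invariant to a constant added to the whole series", {
  g <- gen_perturbation_trial(seed = 21)
  m1 <- reactive_metrics(g$trial)
  tr <- g$trial
  for (nm in names(tr$markers)) tr$markers[[nm]]$values <- tr$markers[[nm]]$values + 7
  m2 <- reactive_metrics(tr)
  expect_equal(m2$rms_com_ap, m1$rms_com_ap, tolerance = 1e-9)
})
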