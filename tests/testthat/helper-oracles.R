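# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: direct summation instead of fft, numeric
# integration instead of pt(), sample-by-sample loops instead of
# vectorized algebra.

# power of a Hann-tapered, demeaned window at one frequency, by direct
# DFT-definition summation (one-sided PSD scaling)
oracle_psd_power <- function(x, fs, f) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  k <- 0:(n - 1)
  re <- sum(x * w * cos(-2 * pi * f * k / fs))
  im <- sum(x * w * sin(-2 * pi * f * k / fs))
  (re^2 + im^2) * 2 / (fs * sum(w^2))
}

# two-sided p value of a one-sample t statistic by numeric integration
# of the t density (gamma-function form)
oracle_t_pvalue <- function(tval, df) {
  dens <- function(u)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(tval), Inf, rel.tol = 1e-12)$value
}

# whole-body COM by an explicit per-sample, per-segment loop
oracle_com_ap <- function(marker_values, segments) {
  n <- length(marker_values[[1]])
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(nrow(segments))) {
      p <- marker_values[[segments$proximal[j]]][i]
      d <- marker_values[[segments$distal[j]]][i]
      acc <- acc + segments$count[j] * segments$mass_fraction[j] *
        (p + segments$com_fraction[j] * (d - p))
    }
    out[i] <- acc
  }
  out
}

# convenience: a marker_set of seeded random smooth trajectories
random_marker_set <- function(seed, n = 400, fs = 200) {
  set.seed(seed)
  mk <- lapply(1:5, function(j) {
    t <- (0:(n - 1)) / fs
    base <- runif(1, -20, 20)
    base + runif(1, 0, 3) * sin(2 * pi * runif(1, 0.3, 2) * t + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, 0.05)
  })
  names(mk) <- c("meta5", "malleolus", "knee", "trochanter", "shoulder")
  list(values = mk,
       set = marker_set(
         meta5 = uniform_ts(mk$meta5, fs), malleolus = uniform_ts(mk$malleolus, fs),
         knee = uniform_ts(mk$knee, fs), trochanter = uniform_ts(mk$trochanter, fs),
         shoulder = uniform_ts(mk$shoulder, fs)))
}

# two-tone 7.5 s window: locomotor tone at 2 Hz (amp 1) plus freeze-band
# tone at 4.8 Hz (both on exact frequency bins of the 7.5 s window)
two_tone_window <- function(freeze_amp, fs = 200, span = 7.5,
                            loco_freq = 2, freeze_freq = 4.8) {
  t <- (0:(round(span * fs) - 1)) / fs
  uniform_ts(sin(2 * pi * loco_freq * t) + freeze_amp * sin(2 * pi * freeze_freq * t),
             fs = fs)
}
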