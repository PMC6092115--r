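test_that("percent_change and improvement_score follow the sign conventions", {
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(1, 2), -0.5)
  expect_error(percent_change(1, 0), "baseline")

  expect_equal(improvement_score("fog_time", -0.4), 0.4)
  expect_equal(improvement_score("apa_amplitude", 0.3), 0.3)
  expect_equal(improvement_score("apa_duration", 0.2), -0.2)
  expect_equal(improvement_score("gait_time", -0.1), 0.1)
  expect_error(improvement_score("updrs", 0.1), "unknown")
})

test_that("ON/OFF swap identity: pct(on, off) = -pct(off, on) * on / off", {
  set.seed(12)
  on <- runif(20, 0.5, 3)
  off <- runif(20, 0.5, 3)
  expect_equal(percent_change(on, off),
               -percent_change(off, on) * on / off, tolerance = 1e-12)
})

test_that("one_sample_t matches the numeric-integration t-CDF oracle", {
  expect_equal(one_sample_t(c(1, -1))$t, 0)
  expect_equal(one_sample_t(c(1, -1))$p, 1.0)
  expect_error(one_sample_t(rep(0.5, 4)), "zero standard deviation")
  expect_error(one_sample_t(0.3), "at least 2")

  vals <- c(0.2, 0.4, 0.1, 0.3)
  r <- one_sample_t(vals)
  expect_equal(r$t, mean(vals) / (sd(vals) / 2), tolerance = 1e-12)
  expect_identical(r$df, 3L)
  expect_equal(r$p, oracle_t_pvalue(r$t, r$df), tolerance = 1e-8)

  set.seed(3)
  for (n in c(2, 4, 9)) {
    v <- rnorm(n, 0.2, 0.5)
    r <- one_sample_t(v)
    expect_equal(r$p, oracle_t_pvalue(r$t, r$df), tolerance = 1e-8)
  }
})

test_that("one_sample_t is invariant to positive scaling", {
  v <- c(0.2, -0.1, 0.5, 0.3, 0.05)
  r1 <- one_sample_t(v)
  for (c in c(0.01, 7, 1e4)) {
    r2 <- one_sample_t(c * v)
    expect_equal(r2$t, r1$t, tolerance = 1e-12)
    expect_equal(r2$p, r1$p, tolerance = 1e-12)
  }
})

make_trials <- function() {
  # 4 subjects x 3 conditions x 2 trials of one variable with exact means
  grid <- expand.grid(subject = sprintf("P%d", 1:4),
                      condition = c("OFF", "HZ60", "HZ300"),
                      trial = 1:2, stringsAsFactors = FALSE)
  # exactly representable multipliers: every subject's percent change is
  # bit-identical, so the degenerate-sample (zero-spread) path is exercised
  base <- c(P1 = 10, P2 = 12, P3 = 8, P4 = 11)
  mult <- c(OFF = 1, HZ60 = 0.5, HZ300 = 0.25)
  grid$variable <- "gait_time"
  # two trials symmetric about the target mean -> trial mean is exact
  grid$value <- base[grid$subject] * mult[grid$condition] +
    ifelse(grid$trial == 1, 0.5, -0.5)
  grid[, c("subject", "condition", "variable", "value")]
}

test_that("summarize_study reproduces a hand-computed percent-change table", {
  res <- summarize_study(make_trials())
  expect_identical(nrow(res$percent_change), 8L)
  expect_equal(res$percent_change$pct_change[res$percent_change$condition == "HZ60"],
               rep(-0.5, 4), tolerance = 1e-12)
  expect_equal(res$percent_change$pct_change[res$percent_change$condition == "HZ300"],
               rep(-0.75, 4), tolerance = 1e-12)
  # gait_time improvement = -pct
  expect_equal(res$percent_change$improvement,
               -res$percent_change$pct_change, tolerance = 1e-12)
  # degenerate: all subjects share the same pct exactly -> sd 0 -> noted, NA stats
  tt <- res$ttests
  expect_true(all(is.na(tt$t)))
  expect_match(tt$note[1], "degenerate")
})

test_that("summarize_study is invariant to row order", {
  tr <- make_trials()
  set.seed(9)
  perm <- tr[sample(nrow(tr)), ]
  a <- summarize_study(tr)
  b <- summarize_study(perm)
  expect_equal(a$summary, b$summary)
  expect_equal(a$percent_change, b$percent_change)
  expect_equal(a$ttests, b$ttests)
})

test_that("zero OFF baselines and missing OFF cells are excluded with a note", {
  tr <- make_trials()
  fog <- tr
  fog$variable <- "fog_time"
  fog$value <- ifelse(fog$subject %in% c("P1", "P4"), 0,
                      fog$value * 0.4) # P1/P4 never freeze
  expect_message(res <- summarize_study(rbind(tr, fog)), "undefined")
  pcf <- res$percent_change[res$percent_change$variable == "fog_time", ]
  expect_setequal(unique(pcf$subject), c("P2", "P3"))

  noOff <- tr[!(tr$subject == "P2" & tr$condition == "OFF"), ]
  expect_message(res2 <- summarize_study(noOff), "no OFF data")
  expect_false("P2" %in% res2$percent_change$subject)
})

test_that("identical ON and OFF data yield all-zero percent change", {
  tr <- make_trials()
  tr$value <- ave(tr$value, tr$subject, FUN = mean) # flatten conditions
  res <- summarize_study(tr)
  expect_true(all(res$percent_change$pct_change == 0))
  expect_true(all(is.na(res$ttests$t)))
})
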