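test_that("periodogram concentrates a commensurate tone in a single bin", {
  x <- sinusoid_series(n_days = 7, period = 1440)$counts
  sp <- periodogram(x)
  k <- which.max(sp$power[1:5041])   # search the non-redundant half grid
  expect_equal(sp$frequency[k], 7 / 10080)   # = 1/1440 cycles per min
  # all other bins empty for an integer number of cycles
  expect_lt(sum(sp$power[-c(k, 10080 - k + 2)]) / sum(sp$power), 1e-20)

  # constant window: no power anywhere after mean removal
  expect_equal(max(periodogram(rep(3, 2880))$power), 0)
  expect_error(periodogram(5), "at least 2")
})

test_that("periodogram satisfies Parseval and ignores additive constants", {
  set.seed(13)
  x <- rnorm(2880)
  sp <- periodogram(x)
  v_n <- mean((x - mean(x))^2)               # variance with denominator N
  expect_equal(sum(sp$power), length(x) * v_n, tolerance = 1e-9)
  expect_equal(periodogram(x + 100)$power, sp$power, tolerance = 1e-6)
})

test_that("tone power at the fundamental bin scales with amplitude squared", {
  t_min <- 0:(10080 - 1)
  p1 <- periodogram(2 * sin(2 * pi * t_min / 1440))
  p2 <- periodogram(6 * sin(2 * pi * t_min / 1440))
  expect_equal(p2$power[8] / p1$power[8], 9, tolerance = 1e-6)
})

test_that("harmonic summary reads the 24-h fundamental and its harmonics", {
  t_min <- 0:(10080 - 1)
  tone24 <- sin(2 * pi * t_min / 1440)
  tone12 <- sin(2 * pi * t_min / 720)

  h24 <- harmonic_summary(periodogram(tone24))
  expect_lt(h24$ratio, 0.01)
  expect_equal(h24$dominant_period, 1440)

  h12 <- harmonic_summary(periodogram(tone12))
  expect_identical(h12$ratio, Inf)          # fundamental power ~ 0
  expect_equal(h12$dominant_period, 720)

  hmix <- harmonic_summary(periodogram(tone24 + tone12))
  expect_equal(hmix$ratio, 1, tolerance = 0.01)

  # grid misalignment is a hard error naming the remedy
  expect_error(harmonic_summary(periodogram(rnorm(5000))), "window length")
})

test_that("rolling harmonic ratios stay low for a stable 24-h rhythm", {
  sim <- generate_circadian_series(circadian_params(n_days = 20, seed = 5))
  r <- rolling_harmonic_ratio(make_windows(sim))
  expect_identical(nrow(r), 14L)
  expect_lt(max(r$ratio), 0.5)
  expect_true(all(r$dominant_period == 1440))
  expect_identical(nrow(detect_rhythm_transition(r)), 0L)
})

test_that("threshold crossings produce WARN then SWITCH events", {
  r <- data.frame(ratio = c(0.1, 0.2, 0.98, 1.3))
  ev <- detect_rhythm_transition(r)
  expect_equal(ev$event, c("WARN", "SWITCH"))
  expect_equal(ev$index, c(3L, 4L))          # third and fourth entries
  expect_equal(ev$ratio, c(0.98, 1.3))

  # raising the warn threshold can only delay the warning
  ev2 <- detect_rhythm_transition(r, warn_threshold = 1.2)
  expect_gte(ev2$index[ev2$event == "WARN"], ev$index[ev$event == "WARN"])

  none <- detect_rhythm_transition(data.frame(ratio = c(0.1, 0.3),
                                              dominant_period = c(1440, 1440)))
  expect_identical(nrow(none), 0L)
})

test_that("a synthetic 24-to-12-hour switch is dated within its first window week", {
  base <- generate_circadian_series(circadian_params(n_days = 80, seed = 11))
  spec <- transition_spec(onset_day = 69, ramp_days = 28, variance_gain = 1,
                          episode_type = "depressive",
                          switch_period = 720, switch_day = 60)
  r <- rolling_harmonic_ratio(make_windows(inject_transition_signature(base, spec)))
  first_high <- r$end_day[which(r$ratio > 1)[1]]
  expect_true(first_high >= 60 && first_high <= 67)
  ev <- detect_rhythm_transition(r)
  sw <- ev[ev$event == "SWITCH", ]
  expect_identical(nrow(sw), 1L)
  expect_true(sw$end_day >= 60 && sw$end_day <= 67)
  expect_equal(sw$dominant_period, 720)
})

test_that("a 24-to-4-hour switch is flagged with dominant period 240", {
  base <- generate_circadian_series(circadian_params(n_days = 40, seed = 17))
  spec <- transition_spec(onset_day = 30, ramp_days = 10, variance_gain = 1,
                          episode_type = "depressive",
                          switch_period = 240, switch_day = 20)
  r <- rolling_harmonic_ratio(make_windows(inject_transition_signature(base, spec)))
  ev <- detect_rhythm_transition(r)
  sw <- ev[ev$event == "SWITCH", ]
  expect_gte(nrow(sw), 1L)
  expect_equal(sw$dominant_period[1], 240)
})
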