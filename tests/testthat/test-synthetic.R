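test_that("the circadian generator is seed-deterministic and non-negative", {
  p <- circadian_params(n_days = 10, seed = 99)
  a <- generate_circadian_series(p)
  b <- generate_circadian_series(p)
  expect_identical(a$counts, b$counts)
  expect_identical(length(a), 10L * 1440L)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$valid))

  # RNG state of the caller is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_circadian_series(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a noiseless generator is a pure 24-h tone over the mesor", {
  flat <- generate_circadian_series(
    circadian_params(n_days = 8, amplitude = 0, noise_sd = 0, mesor = 42))
  expect_equal(unique(flat$counts), 42)

  tone <- generate_circadian_series(
    circadian_params(n_days = 8, amplitude = 10, noise_sd = 0, mesor = 50))
  w <- make_windows(tone)
  for (k in c(1L, 2L)) {
    sp <- periodogram(window_values(w, k))
    peak <- which.max(sp$power[2:5041]) + 1L   # nonzero frequencies
    expect_equal(sp$frequency[peak], 1 / 1440)
  }
})

test_that("signature injection is the identity when it changes nothing", {
  a <- generate_circadian_series(circadian_params(n_days = 40, seed = 2))
  null_spec <- transition_spec(onset_day = 30, ramp_days = 10,
                               variance_gain = 1, episode_type = "manic")
  expect_identical(inject_transition_signature(a, null_spec)$counts, a$counts)
})

test_that("the variance ramp leaves pre-ramp counts unchanged and raises late variance", {
  day_var <- function(x, d) var(x[(d * 1440 + 1):((d + 1) * 1440)])
  ratios <- vapply(1:100, function(seed) {
    a <- generate_circadian_series(circadian_params(n_days = 32, seed = seed))
    spec <- transition_spec(onset_day = 30, ramp_days = 28, variance_gain = 4,
                            episode_type = "depressive")
    b <- inject_transition_signature(a, spec)
    expect_identical(b$counts[1:(2 * 1440)], a$counts[1:(2 * 1440)])
    day_var(b$counts, 29) / day_var(b$counts, 1)
  }, numeric(1))
  expect_gt(mean(ratios), 1)   # last pre-onset day vs pre-ramp day
})

test_that("a rhythm switch flips the harmonic ratio across the switch day", {
  a <- generate_circadian_series(circadian_params(n_days = 30, seed = 4))
  spec <- transition_spec(onset_day = 29, ramp_days = 5, variance_gain = 1,
                          episode_type = "manic",
                          switch_period = 720, switch_day = 15)
  b <- inject_transition_signature(a, spec)
  pre <- harmonic_summary(periodogram(b$counts[1:10080]))
  post <- harmonic_summary(periodogram(b$counts[(15 * 1440 + 1):(22 * 1440)]))
  expect_lt(pre$ratio, 1)
  expect_gt(post$ratio, 1)
})

test_that("transition specs reject impossible geometry", {
  expect_error(transition_spec(onset_day = 10, ramp_days = 20,
                               episode_type = "manic"),
               "before day 0")
  expect_error(transition_spec(onset_day = 10, ramp_days = 5,
                               variance_gain = 0, episode_type = "manic"),
               "positive")
  expect_error(transition_spec(onset_day = 10, ramp_days = 5,
                               episode_type = "manic", switch_period = 720),
               "switch_day")
  a <- generate_circadian_series(circadian_params(n_days = 10))
  expect_error(inject_transition_signature(
    a, transition_spec(onset_day = 20, ramp_days = 5, episode_type = "manic")),
    "outside")
  plain <- activity_series(rep(1, 1440 * 10), start_time = t0)
  expect_error(inject_transition_signature(
    plain, transition_spec(onset_day = 5, ramp_days = 2, episode_type = "manic")),
    "generation parameters")
})

test_that("symptom generator places detectable episodes and nulls never trigger", {
  manic <- generate_symptom_series(
    20, transition_spec(onset_day = 70, ramp_days = 28, variance_gain = 4,
                        episode_type = "manic"), seed = 8)
  on <- detect_episode_onset(manic)
  expect_equal(on$episode_type, "manic")
  expect_equal(on$onset_week_index, 10L)
  expect_true(all(manic$asrm[1:10] <= 5))

  depr <- generate_symptom_series(
    20, transition_spec(onset_day = 70, ramp_days = 28, variance_gain = 4,
                        episode_type = "depressive"), seed = 8)
  ond <- detect_episode_onset(depr)
  expect_equal(ond$episode_type, "depressive")
  expect_equal(ond$onset_week_index, 10L)
  expect_true(all(depr$ids_sr[1:10] <= 25))

  for (seed in 1:20) {
    null <- generate_symptom_series(26, episode = NULL, seed = seed)
    expect_null(detect_episode_onset(null))
  }

  # determinism
  expect_identical(as.data.frame(manic),
                   as.data.frame(generate_symptom_series(
                     20, transition_spec(onset_day = 70, ramp_days = 28,
                                         variance_gain = 4,
                                         episode_type = "manic"), seed = 8)))
})

test_that("simulated patients carry consistent ground truth", {
  spec <- transition_spec(onset_day = 35, ramp_days = 28, variance_gain = 4,
                          episode_type = "depressive")
  sim <- simulate_patient(circadian_params(n_days = 56, seed = 6), spec)
  expect_equal(sim$truth$onset_day, 35L)
  on <- detect_episode_onset(sim$symptoms)
  expect_equal(on$onset_day, 35L)
  expect_equal(on$episode_type, "depressive")
})
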