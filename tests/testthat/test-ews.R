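test_that("window variance matches the n-1 formula and its scaling law", {
  expect_equal(window_variance(c(1, 2, 3, 4)), 5 / 3, tolerance = 1e-6)
  expect_equal(window_variance(rep(4, 100)), 0)
  x <- rnorm(50)
  expect_equal(window_variance(2 * x), 4 * window_variance(x))
  expect_true(is.na(window_variance(c(3, NA, NA))))
})

test_that("Pearson kurtosis matches direct central moments and its bounds", {
  # m2 = 0.1875, m4 = 0.08203125 for three zeros and a one
  expect_equal(window_kurtosis(c(0, 0, 0, 1)), 0.08203125 / 0.1875^2,
               tolerance = 1e-9)
  expect_equal(window_kurtosis(c(0, 0, 0, 1)), 7 / 3, tolerance = 1e-4)
  # symmetric two-point mass attains the Pearson lower bound
  expect_equal(window_kurtosis(c(-1, 1, -1, 1)), 1)
  expect_true(is.na(window_kurtosis(rep(2, 10))))   # zero variance
  expect_true(is.na(window_kurtosis(c(1, 2, 3))))   # too few values

  # Gaussian reference value 3 at the 7-day window size
  set.seed(101)
  expect_equal(window_kurtosis(rnorm(10080)), 3, tolerance = 0.1)

  # kurtosis >= 1 wherever defined, on assorted random windows
  set.seed(7)
  for (i in 1:50) {
    k <- window_kurtosis(rpois(60, lambda = sample(1:20, 1)))
    if (!is.na(k)) expect_gte(k, 1)
  }
})

test_that("lag autocorrelation reads circadian phase as expected", {
  s24 <- sinusoid_series(n_days = 7, period = 1440)$counts
  s12 <- sinusoid_series(n_days = 7, period = 720)$counts
  expect_equal(acf_at_lag(s24, 720), -1, tolerance = 0.01)   # antiphase
  expect_equal(acf_at_lag(s24, 1440), 1, tolerance = 0.01)   # in phase
  expect_equal(acf_at_lag(s12, 720), 1, tolerance = 0.01)    # deregulated case
  expect_error(acf_at_lag(s24, 20000), "inside the window")

  # bounded on random inputs
  set.seed(11)
  for (i in 1:30) {
    r <- acf_at_lag(rnorm(500), sample(1:100, 1))
    expect_true(abs(r) <= 1 + 1e-8)
  }
})

test_that("masked computation equals computing on the deleted-value vector", {
  set.seed(21)
  x <- rgamma(300, 2, 0.1)
  x[sample(300, 40)] <- NA
  kept <- x[!is.na(x)]
  expect_equal(window_variance(x), window_variance(kept))
  expect_equal(window_kurtosis(x), window_kurtosis(kept))
})

test_that("rolling indicators align with windows and respect invariances", {
  set.seed(31)
  n_days <- 12L
  t_min <- 0:(n_days * 1440 - 1)
  x <- pmax(0, 50 + 40 * cos(2 * pi * t_min / 1440) + rnorm(length(t_min), 0, 10))
  s <- activity_series(x, start_time = t0)
  e <- rolling_ews(make_windows(s))
  expect_identical(nrow(e), n_days - 6L)
  expect_named(e, c("end_day", "variance", "kurtosis", "acf720", "usable"))
  expect_false(anyNA(e$variance))

  # affine transforms (a > 0) leave kurtosis and acf unchanged, variance x a^2
  s2 <- activity_series(3 * x + 17, start_time = t0)
  e2 <- rolling_ews(make_windows(s2))
  expect_equal(e2$kurtosis, e$kurtosis, tolerance = 1e-9)
  expect_equal(e2$acf720, e$acf720, tolerance = 1e-9)
  expect_equal(e2$variance, 9 * e$variance, tolerance = 1e-9)

  # each windowed value equals a from-scratch computation on the slice
  k <- 3
  slice <- x[(2 * 1440 + 1):(2 * 1440 + 10080)]
  expect_equal(e$variance[k], window_variance(slice))
  expect_equal(e$kurtosis[k], window_kurtosis(slice))
  expect_equal(e$acf720[k], acf_at_lag(slice, 720))
})

test_that("constant series yield zero variance and undefined shape indicators", {
  s <- activity_series(rep(5, 7 * 1440), start_time = t0)
  e <- rolling_ews(make_windows(s))
  expect_equal(e$variance, 0)
  expect_true(is.na(e$kurtosis) && is.na(e$acf720))
})

test_that("mean-activity comparisons label the published examples correctly", {
  expect_equal(compare_mean_activity(96.1, 139.1)$label, "more")
  expect_equal(compare_mean_activity(153.8, 124.6)$label, "less")
  expect_equal(compare_mean_activity(100, 100)$label, "equal")

  # every row of the reference tables is labelled consistently
  for (period in c("pre_onset", "during_episode")) {
    ref <- load_reference_activity(period)
    lab <- mapply(function(r, t) compare_mean_activity(r, t)$label,
                  ref$mean_euthymic, ref$mean_episode)
    expect_equal(unname(lab), ref$interpretation)
  }
})

test_that("interval means use raw counts over half-open day intervals", {
  x <- rep(c(10, 30), each = 1440)       # day 0 mean 10, day 1 mean 30
  s <- activity_series(c(x, rep(20, 5 * 1440)), start_time = t0)
  expect_equal(interval_mean(s, c(0, 1)), 10)
  expect_equal(interval_mean(s, c(1, 2)), 30)
  expect_equal(interval_mean(s, c(0, 2)), 20)
  expect_error(interval_mean(s, c(6, 9)), "span")
})
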