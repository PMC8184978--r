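#' Sample variance of a window
#'
#' Variance over observed epochs with denominator `n - 1`. Returns `NA` when
#' fewer than two epochs are observed.
#'
#' @param values Numeric window; `NA` marks missing epochs.
#' @return Scalar variance, or `NA`.
#' @export
window_variance <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) return(NA_real_)
  stats::var(x)
}

#' Pearson kurtosis of a window
#'
#' Raw (non-excess) kurtosis `m4 / m2^2`, with central moments computed with
#' denominator `n` over observed epochs — the convention of the resilience-
#' indicator literature. The Gaussian reference value is 3; the Pearson lower
#' bound is 1. Returns `NA` for fewer than 4 observations or zero variance.
#'
#' @param values Numeric window; `NA` marks missing epochs.
#' @return Scalar kurtosis, or `NA`.
#' @export
window_kurtosis <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) return(NA_real_)
  mean(xc^4) / m2^2
}

#' Autocorrelation at a fixed lag
#'
#' Autocorrelation estimator
#' `sum_t (x_t - xbar)(x_{t+lag} - xbar) / sum_t (x_t - xbar)^2`, with `xbar`
#' the full-window mean over observed epochs and both sums running over the
#' pairs `(t, t+lag)` where both epochs are observed, so a pure periodic
#' signal in phase opposition attains -1. At lag 720 (12 h) on minute-level
#' activity this contrasts day with night: a strong 24-h rhythm gives values
#' near -1, a deregulated 12-h rhythm drives it towards +1.
#'
#' @param values Numeric window; `NA` marks missing epochs.
#' @param lag Lag in epochs (minutes).
#' @return Scalar autocorrelation in `[-1, 1]`, or `NA` when the window has
#'   zero variance or fewer than 2 complete pairs.
#' @export
acf_at_lag <- function(values, lag = 720L) {
  lag <- as.integer(lag)
  n <- length(values)
  if (lag < 1L || lag >= n) stop("lag must lie strictly inside the window")
  ok <- !is.na(values)
  if (sum(ok) < 2L) return(NA_real_)
  xc <- values - mean(values[ok])
  a <- xc[1:(n - lag)]
  b <- xc[(lag + 1L):n]
  pair <- !is.na(a) & !is.na(b)
  if (sum(pair) < 2L) return(NA_real_)
  den <- sum(a[pair]^2)
  if (den <= 0) return(NA_real_)
  sum(a[pair] * b[pair]) / den
}

#' Rolling early-warning indicators
#'
#' Applies [window_variance()], [window_kurtosis()] and [acf_at_lag()] to
#' every window; windows below the completeness threshold yield `NA` for all
#' three indicators.
#'
#' @param windowed A `windowed_series` from [make_windows()], normally built
#'   from a [detrend_linear()] residual series.
#' @param lag Autocorrelation lag in minutes (default 720 = 12 h).
#' @return A data frame of class `ews_frame` with columns `end_day`,
#'   `variance`, `kurtosis`, `acf720` (named after the lag) and `usable`.
#' @export
rolling_ews <- function(windowed, lag = 720L) {
  stopifnot(inherits(windowed, "windowed_series"))
  if (!any(windowed$usable)) stop("no usable windows")
  n_win <- length(windowed$end_day)
  v <- k <- a <- rep(NA_real_, n_win)
  for (i in seq_len(n_win)) {
    if (!windowed$usable[i]) next
    x <- window_values(windowed, i)
    v[i] <- window_variance(x)
    k[i] <- window_kurtosis(x)
    a[i] <- acf_at_lag(x, lag)
  }
  out <- data.frame(end_day = windowed$end_day, variance = v, kurtosis = k,
                    acf = a, usable = windowed$usable)
  names(out)[4L] <- paste0("acf", lag)
  attr(out, "lag") <- as.integer(lag)
  class(out) <- c("ews_frame", "data.frame")
  out
}

#' Mean activity over a day interval
#'
#' Mean of the raw (non-detrended) counts over the half-open day interval
#' `[start_day, end_day)`, 0-based from the series start.
#'
#' @param series An [activity_series()] of raw counts.
#' @param interval Length-2 numeric `c(start_day, end_day)`.
#' @return Scalar mean count.
#' @export
interval_mean <- function(series, interval) {
  stopifnot(inherits(series, "activity_series"), length(interval) == 2L)
  lo <- as.integer(interval[1L]) * 1440L + 1L
  hi <- as.integer(interval[2L]) * 1440L
  n <- length(series$counts)
  if (interval[1L] < 0 || lo > hi || hi > n) {
    stop("interval outside the series span")
  }
  x <- series$counts[lo:hi]
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop("no observed epochs in interval")
  mean(x)
}

#' Compare mean activity between two 7-day periods
#'
#' Labels the target period (typically the 7 days immediately before episode
#' onset, or the first 7 days of the episode) against the euthymic reference
#' period. Higher pre-onset activity is the expected signature of an upcoming
#' manic episode, lower of a depressive one.
#'
#' @param reference_mean Mean counts of the euthymic reference period.
#' @param target_mean Mean counts of the comparison period.
#' @return An object of class `mean_activity_comparison` with fields
#'   `reference_mean`, `target_mean` and `label` ("more", "less" or "equal").
#' @export
compare_mean_activity <- function(reference_mean, target_mean) {
  if (!is.finite(reference_mean) || !is.finite(target_mean)) {
    stop("both means must be defined")
  }
  d <- target_mean - reference_mean
  label <- if (d > 0) "more" else if (d < 0) "less" else "equal"
  structure(list(reference_mean = reference_mean, target_mean = target_mean,
                 label = label),
            class = "mean_activity_comparison")
}

#' @export
print.mean_activity_comparison <- function(x, ...) {
  cat(sprintf("%s activity in target period (%.1f) vs reference (%.1f)\n",
              x$label, x$target_mean, x$reference_mean))
  invisible(x)
}
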