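#' Rolling-window specification
#'
#' Defines the sliding window all indicators share: 7 days of 1-minute epochs
#' advanced by 1 day, so every window spans at least one full weekend and the
#' indicator series has daily resolution. Windows whose observed fraction
#' falls below `min_completeness` are emitted but flagged unusable.
#'
#' @param window_length Window length in minutes (default 10080 = 7 days).
#' @param step Step between window starts in minutes (default 1440 = 1 day).
#' @param min_completeness Minimum fraction of observed epochs in a usable
#'   window, in `[0, 1]` (default 0.9).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_length = 10080L, step = 1440L,
                        min_completeness = 0.9) {
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (step < 1L || window_length < step) {
    stop("window_length must be >= step >= 1 minute")
  }
  if (window_length %% step != 0L) {
    stop("window_length must be a multiple of step")
  }
  if (min_completeness < 0 || min_completeness > 1) {
    stop("min_completeness must lie in [0, 1]")
  }
  structure(list(window_length = window_length, step = step,
                 min_completeness = min_completeness),
            class = "window_spec")
}

#' Remove the global linear trend from an activity series
#'
#' Fits an ordinary-least-squares line to the observed counts with elapsed
#' time in minutes as the regressor and returns the residual series. Variance,
#' kurtosis and autocorrelation are all sensitive to slow drift, so the trend
#' is removed once, globally, before windowing. Missing epochs stay missing;
#' residuals may be negative.
#'
#' @param series An [activity_series()].
#' @return An [activity_series()] of residuals (`detrended = TRUE`).
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  x <- series$counts
  ok <- series$valid
  if (sum(ok) < 2L) stop("detrending needs at least 2 observed epochs")
  t_min <- as.numeric(seq_along(x) - 1L)
  tm <- t_min[ok]
  xm <- x[ok]
  tbar <- mean(tm)
  slope <- sum((tm - tbar) * xm) / sum((tm - tbar)^2)
  intercept <- mean(xm) - slope * tbar
  res <- x - (intercept + slope * t_min)
  activity_series(res, start_time = series$start_time,
                  patient_id = series$patient_id, valid = ok,
                  detrended = TRUE)
}

#' Cut an activity series into rolling windows
#'
#' Emits only full windows: window `k` (1-based) covers epochs
#' `[(k-1)*step, (k-1)*step + window_length)` of the series, half-open,
#' 0-based. Each window is labelled by the 0-based calendar day on which it
#' ends, so a 7-day window over days 0..6 carries `end_day = 7` and the
#' indicator value dated day `d` uses only data observed strictly before
#' day `d`.
#'
#' @param series An [activity_series()].
#' @param spec A [window_spec()].
#' @return An object of class `windowed_series` with fields `end_day`,
#'   `completeness`, `usable`, plus the spec and the source series. Window
#'   contents are extracted lazily with [window_values()].
#' @export
make_windows <- function(series, spec = window_spec()) {
  stopifnot(inherits(series, "activity_series"), inherits(spec, "window_spec"))
  n <- length(series$counts)
  wl <- spec$window_length
  if (n < wl) stop("series shorter than one full window")
  n_win <- (n - wl) %/% spec$step + 1L
  starts <- (seq_len(n_win) - 1L) * spec$step
  end_day <- (starts + wl) %/% 1440L
  completeness <- vapply(starts, function(s) {
    mean(series$valid[(s + 1L):(s + wl)])
  }, numeric(1))
  structure(
    list(end_day = end_day, start_epoch = starts,
         completeness = completeness,
         usable = completeness >= spec$min_completeness,
         spec = spec, series = series),
    class = "windowed_series"
  )
}

#' @export
length.windowed_series <- function(x) length(x$end_day)

#' @export
print.windowed_series <- function(x, ...) {
  cat(sprintf("<windowed_series> %d windows of %d min, step %d min; %d usable\n",
              length(x$end_day), x$spec$window_length, x$spec$step,
              sum(x$usable)))
  invisible(x)
}

#' Extract one window's epoch values
#'
#' @param windowed A `windowed_series` from [make_windows()].
#' @param k 1-based window index.
#' @return Numeric vector of length `window_length`; `NA` at missing epochs.
#' @export
window_values <- function(windowed, k) {
  stopifnot(inherits(windowed, "windowed_series"))
  k <- as.integer(k)
  if (k < 1L || k > length(windowed$end_day)) stop("window index out of range")
  s <- windowed$start_epoch[k]
  windowed$series$counts[(s + 1L):(s + windowed$spec$window_length)]
}
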