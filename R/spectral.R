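#' Unsmoothed FFT periodogram of a window
#'
#' Discrete-Fourier periodogram of a mean-removed window on the natural
#' frequency grid `k/N` cycles per minute, with no tapering or smoothing.
#' Ordinates are `|X_k|^2 / N` in squared count units, so their sum over the
#' full grid equals `N` times the sample variance (denominator `N`) —
#' Parseval's identity. Missing epochs are filled with the window mean before
#' transforming, which leaves them spectrally silent.
#'
#' @param values Numeric window; `NA` marks missing epochs.
#' @param window_end_day Optional integer label carried into the result.
#' @return An object of class `activity_spectrum`: list with `frequency`
#'   (cycles/min, `k/N` for `k = 0..N-1`), `power`, `n` and `window_end_day`.
#' @export
periodogram <- function(values, window_end_day = NA_integer_) {
  n <- length(values)
  if (n < 2L) stop("periodogram needs at least 2 epochs")
  ok <- !is.na(values)
  if (!any(ok)) stop("periodogram needs at least one observed epoch")
  x <- values
  x[!ok] <- mean(values[ok])
  x <- x - mean(x)
  pw <- Mod(stats::fft(x))^2 / n
  structure(list(frequency = (seq_len(n) - 1L) / n, power = pw, n = n,
                 window_end_day = window_end_day),
            class = "activity_spectrum")
}

#' @export
print.activity_spectrum <- function(x, ...) {
  k <- which.max(x$power[-1L]) + 1L
  cat(sprintf("<activity_spectrum> N = %d; peak at %.3g cycles/min (period %.0f min)\n",
              x$n, x$frequency[k], 1 / x$frequency[k]))
  invisible(x)
}

#' Fundamental and harmonic power summary
#'
#' Reads spectral density at the 24-h fundamental (period 1440 min) and its
#' harmonics at periods `1440/n` for `n = 2..n_harmonics`, and forms the
#' harmonic ratio: second-harmonic (12-h) power divided by fundamental power.
#' Ratios approaching or exceeding 1 indicate a 12-h rhythm displacing the
#' normal 24-h sleep/wake cycle. The window length must be an exact multiple
#' of the fundamental period so these periods fall on the frequency grid.
#'
#' @param spectrum An `activity_spectrum` from [periodogram()].
#' @param fundamental_period Fundamental period in minutes (default 1440).
#' @param n_harmonics Highest harmonic read (default 6, covering the 12-h and
#'   4-h phenomena while avoiding leakage-driven spurious dominants).
#' @return An object of class `harmonic_summary`: list with
#'   `fundamental_period`, `fundamental_power`, `harmonic_powers` (named by
#'   harmonic number, entries for `n = 2..n_harmonics`), `ratio` (`Inf` when
#'   the fundamental power is below `1e-12` of total power) and
#'   `dominant_period` (argmax over the candidate periods `1440/n`).
#' @export
harmonic_summary <- function(spectrum, fundamental_period = 1440L,
                             n_harmonics = 6L) {
  stopifnot(inherits(spectrum, "activity_spectrum"))
  N <- spectrum$n
  if (N %% fundamental_period != 0L) {
    stop(sprintf(paste0("window length %d is not a multiple of the fundamental ",
                        "period %d min; choose a window length that is"),
                 N, fundamental_period))
  }
  k0 <- N %/% fundamental_period
  harmonics <- seq_len(n_harmonics)
  pw <- spectrum$power[harmonics * k0 + 1L]
  names(pw) <- harmonics
  total <- sum(spectrum$power)
  ratio <- if (pw[1L] < 1e-12 * total) Inf else unname(pw[2L] / pw[1L])
  structure(
    list(fundamental_period = fundamental_period,
         fundamental_power = unname(pw[1L]),
         harmonic_powers = pw[-1L],
         ratio = ratio,
         dominant_period = fundamental_period / harmonics[which.max(pw)],
         window_end_day = spectrum$window_end_day),
    class = "harmonic_summary"
  )
}

#' @export
print.harmonic_summary <- function(x, ...) {
  cat(sprintf("harmonic ratio %.3g (dominant period %.0f min)\n",
              x$ratio, x$dominant_period))
  invisible(x)
}

#' Rolling harmonic-ratio series
#'
#' Computes one [harmonic_summary()] per usable window. Spectra are taken on
#' raw (non-detrended) counts with per-window mean removal, so the DC
#' ordinate cannot dwarf the rhythm peaks; windows below the completeness
#' threshold are skipped.
#'
#' @param windowed A `windowed_series` from [make_windows()] on raw counts.
#' @inheritParams harmonic_summary
#' @return A data frame with one row per usable window: `end_day`, `ratio`,
#'   `dominant_period`, `fundamental_power`, `harmonic2_power`.
#' @export
rolling_harmonic_ratio <- function(windowed, fundamental_period = 1440L,
                                   n_harmonics = 6L) {
  stopifnot(inherits(windowed, "windowed_series"))
  keep <- which(windowed$usable)
  if (length(keep) < 1L) stop("no usable windows")
  rows <- lapply(keep, function(i) {
    hs <- harmonic_summary(
      periodogram(window_values(windowed, i), windowed$end_day[i]),
      fundamental_period = fundamental_period, n_harmonics = n_harmonics
    )
    data.frame(end_day = windowed$end_day[i], ratio = hs$ratio,
               dominant_period = hs$dominant_period,
               fundamental_power = hs$fundamental_power,
               harmonic2_power = unname(hs$harmonic_powers["2"]))
  })
  do.call(rbind, rows)
}

#' Detect rhythm-transition events from a harmonic-ratio series
#'
#' Scans the daily harmonic-ratio series and emits a `WARN` event at the
#' first day the ratio reaches `warn_threshold`, and a `SWITCH` event at the
#' first day the dominant period moves off the 24-h fundamental (any of the
#' candidate harmonic periods, e.g. 12-h or 4-h). When the input carries no
#' `dominant_period` column, `SWITCH` falls back to the ratio reaching
#' `switch_threshold`.
#'
#' @param summaries Data frame from [rolling_harmonic_ratio()] (or any frame
#'   with a `ratio` column and optionally `end_day`, `dominant_period`).
#' @param warn_threshold Ratio triggering a warning (default 0.9).
#' @param switch_threshold Ratio treated as a completed switch when no
#'   dominant-period information is available (default 1.0).
#' @return Data frame of events with columns `event`, `index` (1-based row),
#'   `end_day`, `ratio`, `dominant_period`; zero rows when nothing triggers.
#' @export
detect_rhythm_transition <- function(summaries, warn_threshold = 0.9,
                                     switch_threshold = 1.0) {
  stopifnot(is.data.frame(summaries), "ratio" %in% names(summaries))
  if (nrow(summaries) < 1L) stop("at least one summary is required")
  end_day <- if ("end_day" %in% names(summaries)) summaries$end_day
             else seq_len(nrow(summaries))
  dom <- if ("dominant_period" %in% names(summaries)) summaries$dominant_period
         else rep(NA_real_, nrow(summaries))
  events <- list()
  wi <- which(summaries$ratio >= warn_threshold)[1L]
  if (!is.na(wi)) {
    events$warn <- data.frame(event = "WARN", index = wi, end_day = end_day[wi],
                              ratio = summaries$ratio[wi],
                              dominant_period = dom[wi])
  }
  si <- if (all(is.na(dom))) which(summaries$ratio >= switch_threshold)[1L]
        else which(!is.na(dom) & dom != 1440)[1L]
  if (!is.na(si)) {
    events$switch <- data.frame(event = "SWITCH", index = si,
                                end_day = end_day[si],
                                ratio = summaries$ratio[si],
                                dominant_period = dom[si])
  }
  if (length(events) == 0L) {
    return(data.frame(event = character(), index = integer(),
                      end_day = numeric(), ratio = numeric(),
                      dominant_period = numeric()))
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out[order(out$index), , drop = FALSE]
}
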