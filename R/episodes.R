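first_run_start <- function(flag, min_len) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_len)
  if (length(hit) == 0L) return(NA_integer_)
  c(start = starts[hit[1L]], length = r$lengths[hit[1L]])
}

#' Detect the first mood-episode onset from weekly symptom scores
#'
#' A manic episode starts at the first week beginning a run of at least 2
#' consecutive weeks with ASRM strictly greater than 5; a depressive episode
#' at the first week beginning a run of at least 3 consecutive weeks with
#' IDS-SR strictly greater than 25. Scores exactly at the threshold do not
#' qualify, and missing weeks break runs. The earliest qualifying onset of
#' either type is returned; a same-week tie between the two types is an
#' error requiring manual adjudication.
#'
#' @param q A [symptom_series()].
#' @return An object of class `episode_onset` — list with `episode_type`
#'   ("manic" or "depressive"), `onset_week_index` (0-based),
#'   `onset_date` (that week's start), `onset_day` (0-based day index from
#'   the first assessment week) and `qualifying_run_length` — or `NULL` when
#'   no run qualifies.
#' @export
detect_episode_onset <- function(q) {
  stopifnot(inherits(q, "symptom_series"))
  if (length(q$asrm) < 2L) stop("at least 2 weeks of data are required")
  manic <- first_run_start(q$asrm > 5L, 2L)
  depr <- first_run_start(q$ids_sr > 25L, 3L)
  if (all(is.na(manic)) && all(is.na(depr))) return(NULL)
  m_start <- if (all(is.na(manic))) Inf else manic["start"]
  d_start <- if (all(is.na(depr))) Inf else depr["start"]
  if (m_start == d_start) {
    stop("manic and depressive criteria first qualify in the same week; adjudicate manually")
  }
  if (m_start < d_start) {
    type <- "manic"; run <- manic
  } else {
    type <- "depressive"; run <- depr
  }
  week0 <- as.integer(run["start"]) - 1L
  structure(
    list(episode_type = type, onset_week_index = week0,
         onset_date = q$week_start_dates[week0 + 1L],
         onset_day = 7L * week0,
         qualifying_run_length = as.integer(run["length"])),
    class = "episode_onset"
  )
}

#' @export
print.episode_onset <- function(x, ...) {
  cat(sprintf("%s episode onset at week %d (%s), qualifying run %d weeks\n",
              x$episode_type, x$onset_week_index, format(x$onset_date),
              x$qualifying_run_length))
  invisible(x)
}

#' Pre-onset and euthymic analysis intervals
#'
#' The pre-onset interval is the up-to-four-week span
#' `[max(0, onset_day - 28), onset_day)` on which indicator trends are
#' tested; four weeks allows a plausible extent of time for early-warning
#' signals to develop while keeping the test window close to the transition.
#' The euthymic reference interval is either supplied explicitly or derived
#' automatically as the longest run of weeks with ASRM <= 5 and IDS-SR <= 25
#' that precedes the pre-onset interval.
#'
#' @param onset An `episode_onset` from [detect_episode_onset()].
#' @param series_days Total span of the activity series in days.
#' @param euthymic Optional explicit day interval `c(start, end)`, half-open.
#' @param q Optional [symptom_series()] used for the automatic euthymic rule.
#' @return An object of class `analysis_intervals`: list with `pre_onset`
#'   (half-open day interval), `euthymic` (half-open day interval or `NULL`)
#'   and `pre_onset_n`, the number of rolling-window end days (>= 7) falling
#'   inside the pre-onset interval.
#' @export
analysis_intervals <- function(onset, series_days, euthymic = NULL, q = NULL) {
  stopifnot(inherits(onset, "episode_onset"))
  onset_day <- onset$onset_day
  if (onset_day <= 0L) stop("onset on day 0: no pre-onset data to analyse")
  if (onset_day > series_days) stop("onset lies outside the series span")
  pre <- c(max(0L, onset_day - 28L), onset_day)
  if (is.null(euthymic) && !is.null(q)) {
    calm <- q$asrm <= 5L & q$ids_sr <= 25L
    calm[is.na(calm)] <- FALSE
    n_pre_weeks <- pre[1L] %/% 7L
    calm <- calm[seq_len(min(length(calm), n_pre_weeks))]
    if (any(calm)) {
      r <- rle(calm)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      best <- runs[which.max(r$lengths[runs])]
      euthymic <- 7L * c(starts[best] - 1L, ends[best])
    }
  }
  if (!is.null(euthymic)) {
    euthymic <- as.integer(euthymic)
    if (length(euthymic) != 2L || euthymic[1L] >= euthymic[2L]) {
      stop("euthymic interval must be a half-open day interval c(start, end)")
    }
    if (euthymic[2L] > pre[1L] && euthymic[1L] < pre[2L]) {
      stop("euthymic interval overlaps the pre-onset interval")
    }
  }
  structure(
    list(pre_onset = pre, euthymic = euthymic,
         pre_onset_n = max(0L, pre[2L] - max(pre[1L], 7L))),
    class = "analysis_intervals"
  )
}

#' @export
print.analysis_intervals <- function(x, ...) {
  cat(sprintf("pre-onset days [%d, %d), n = %d indicator days",
              x$pre_onset[1L], x$pre_onset[2L], x$pre_onset_n))
  if (!is.null(x$euthymic)) {
    cat(sprintf("; euthymic days [%d, %d)", x$euthymic[1L], x$euthymic[2L]))
  }
  cat("\n")
  invisible(x)
}
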