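#' Minute-epoch actigraphy series
#'
#' Container for a uniformly spaced 1-minute-epoch activity-count series as
#' produced by a wrist-worn actigraph. Missing epochs (off-wrist periods,
#' device gaps) are carried explicitly through `valid`, never as zero counts:
#' zero is a legitimate activity value during sleep.
#'
#' @param counts Numeric vector of activity counts; `NA` for missing epochs.
#'   Observed values must be finite and non-negative.
#' @param start_time `POSIXct` timestamp of the first epoch.
#' @param patient_id Opaque label for the wearer.
#' @param valid Logical vector flagging observed epochs; defaults to
#'   `!is.na(counts)`.
#' @param detrended Logical; `TRUE` marks a series of regression residuals,
#'   for which the non-negativity constraint is lifted.
#'
#' @return An object of class `activity_series`: a list with elements
#'   `patient_id`, `start_time`, `epoch_mins` (always 1), `counts`, `valid`
#'   and `detrended`.
#' @export
activity_series <- function(counts, start_time, patient_id = "unknown",
                            valid = !is.na(counts), detrended = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("activity series must contain at least one epoch")
  if (!inherits(start_time, "POSIXct")) {
    start_time <- as.POSIXct(start_time, tz = "UTC")
  }
  if (length(start_time) != 1L || is.na(start_time)) {
    stop("start_time must be a single valid timestamp")
  }
  if (length(valid) != length(counts)) {
    stop("valid mask and counts must have the same length")
  }
  valid <- as.logical(valid) & !is.na(counts)
  counts[!valid] <- NA_real_
  obs <- counts[valid]
  if (any(!is.finite(obs))) stop("observed counts must be finite")
  if (!detrended && any(obs < 0)) stop("activity counts must be non-negative")
  structure(
    list(patient_id = as.character(patient_id), start_time = start_time,
         epoch_mins = 1L, counts = counts, valid = valid,
         detrended = isTRUE(detrended)),
    class = "activity_series"
  )
}

#' @export
length.activity_series <- function(x) length(x$counts)

#' @export
print.activity_series <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf("<activity_series> patient %s: %d one-minute epochs (%.1f days)\n",
              x$patient_id, n, n / 1440))
  cat(sprintf("  start %s | %.1f%% observed%s\n",
              format(x$start_time, "%Y-%m-%d %H:%M"),
              100 * mean(x$valid),
              if (x$detrended) " | detrended residuals" else ""))
  invisible(x)
}

#' @export
as.data.frame.activity_series <- function(x, ...) {
  data.frame(
    timestamp = x$start_time + 60 * (seq_along(x$counts) - 1L),
    counts = x$counts
  )
}

#' Weekly symptom-questionnaire series
#'
#' Weekly self-rated mood scores: the Altman Self-Rating Mania scale (ASRM,
#' 0-20) and the Inventory of Depressive Symptomatology, Self-Rated (IDS-SR,
#' 0-84). Consecutive assessments must be exactly 7 days apart.
#'
#' @param week_start_dates `Date` vector of week starts, strictly increasing,
#'   consecutive entries 7 days apart.
#' @param asrm Integer ASRM scores in 0-20, `NA` for missed weeks.
#' @param ids_sr Integer IDS-SR scores in 0-84, `NA` for missed weeks.
#' @param patient_id Opaque label for the respondent.
#'
#' @return An object of class `symptom_series`.
#' @export
symptom_series <- function(week_start_dates, asrm, ids_sr,
                           patient_id = "unknown") {
  week_start_dates <- as.Date(week_start_dates)
  n <- length(week_start_dates)
  if (n < 1L) stop("symptom series must contain at least one week")
  if (anyNA(week_start_dates)) stop("week_start_date entries must be parseable dates")
  if (n > 1L && any(diff(as.integer(week_start_dates)) != 7L)) {
    bad <- which(diff(as.integer(week_start_dates)) != 7L)[1L]
    stop(sprintf("weeks must be exactly 7 days apart (rows %d and %d are not)",
                 bad, bad + 1L))
  }
  if (length(asrm) != n || length(ids_sr) != n) {
    stop("asrm and ids_sr must have one entry per week")
  }
  check_range <- function(x, lo, hi, name) {
    obs <- x[!is.na(x)]
    if (any(obs < lo | obs > hi)) {
      stop(sprintf("%s scores must lie in %d-%d", name, lo, hi))
    }
    as.integer(x)
  }
  structure(
    list(patient_id = as.character(patient_id),
         week_start_dates = week_start_dates,
         asrm = check_range(asrm, 0L, 20L, "ASRM"),
         ids_sr = check_range(ids_sr, 0L, 84L, "IDS-SR")),
    class = "symptom_series"
  )
}

#' @export
print.symptom_series <- function(x, ...) {
  cat(sprintf("<symptom_series> patient %s: %d weekly assessments from %s\n",
              x$patient_id, length(x$asrm), format(x$week_start_dates[1L])))
  invisible(x)
}

#' @export
as.data.frame.symptom_series <- function(x, ...) {
  data.frame(week_start_date = x$week_start_dates,
             asrm = x$asrm, ids_sr = x$ids_sr)
}

parse_timestamps <- function(ts, path) {
  out <- as.POSIXct(ts, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M"))
  if (anyNA(out)) {
    stop(sprintf("%s: unparseable timestamp at row %d ('%s')",
                 path, which(is.na(out))[1L], ts[which(is.na(out))[1L]]))
  }
  out
}

#' Read an actigraphy count table
#'
#' Reads a delimited text table with header columns `timestamp` (ISO-8601
#' local wall-clock time at 1-minute resolution) and `counts` (non-negative
#' integers; empty or `NA` for off-wrist epochs). Gaps in the timestamp grid
#' are filled with missing epochs so that the returned series is uniformly
#' spaced at one minute.
#'
#' @param path Path to the table.
#' @param patient_id Label attached to the returned series.
#' @param sep Field separator (default comma).
#' @return An [activity_series()].
#' @export
read_activity_table <- function(path, patient_id = "unknown", sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("timestamp", "counts") %in% names(tab))) {
    stop(sprintf("%s: expected columns 'timestamp' and 'counts'", path))
  }
  ts <- parse_timestamps(tab$timestamp, path)
  mins <- as.numeric(difftime(ts, ts[1L], units = "mins"))
  if (any(abs(mins - round(mins)) > 1e-6)) {
    stop(sprintf("%s: timestamps must fall on a 1-minute grid (row %d)",
                 path, which(abs(mins - round(mins)) > 1e-6)[1L]))
  }
  mins <- as.integer(round(mins))
  if (anyDuplicated(mins)) {
    stop(sprintf("%s: duplicate timestamp at row %d", path, anyDuplicated(mins)))
  }
  if (is.unsorted(mins, strictly = TRUE)) {
    bad <- which(diff(mins) <= 0)[1L]
    stop(sprintf("%s: timestamps not strictly increasing at row %d", path, bad + 1L))
  }
  raw <- suppressWarnings(as.numeric(tab$counts))
  bad_num <- !is.na(tab$counts) & nzchar(trimws(tab$counts)) & is.na(raw)
  if (any(bad_num)) {
    stop(sprintf("%s: non-numeric count at row %d", path, which(bad_num)[1L]))
  }
  if (any(raw < 0, na.rm = TRUE)) {
    stop(sprintf("%s: negative count at row %d", path, which(raw < 0)[1L]))
  }
  counts <- rep(NA_real_, mins[length(mins)] + 1L)
  counts[mins + 1L] <- raw
  activity_series(counts, start_time = ts[1L], patient_id = patient_id)
}

#' Write an actigraphy count table
#'
#' Inverse of [read_activity_table()]: one row per epoch, missing epochs
#' written with an empty count field so the round trip is the identity.
#'
#' @param series An [activity_series()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "activity_series"))
  df <- as.data.frame(series)
  df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a weekly symptom table
#'
#' Expects header columns `week_start_date` (ISO dates, 7 days apart),
#' `asrm` (0-20) and `ids_sr` (0-84); empty fields mark missed assessments.
#'
#' @param path Path to the table.
#' @param patient_id Label attached to the returned series.
#' @param sep Field separator.
#' @return A [symptom_series()].
#' @export
read_symptom_table <- function(path, patient_id = "unknown", sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("week_start_date", "asrm", "ids_sr")
  if (!all(need %in% names(tab))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  symptom_series(as.Date(tab$week_start_date), tab$asrm, tab$ids_sr,
                 patient_id = patient_id)
}

#' Write a weekly symptom table
#'
#' @param series A [symptom_series()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_symptom_table <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "symptom_series"))
  utils::write.table(as.data.frame(series), path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
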