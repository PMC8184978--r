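#' Analysis configuration
#'
#' Collects the tunable parameters of the per-patient pipeline.
#'
#' @param spec A [window_spec()].
#' @param lag Autocorrelation lag in minutes (default 720).
#' @param alpha Two-sided significance level (significance means
#'   `p <= alpha`; default 0.05).
#' @param warn_threshold,switch_threshold Harmonic-ratio thresholds for
#'   [detect_rhythm_transition()].
#' @param euthymic Optional explicit euthymic day interval `c(start, end)`;
#'   `NULL` selects it automatically from the symptom scores.
#' @return An object of class `bdews_config`.
#' @export
analysis_config <- function(spec = window_spec(), lag = 720L, alpha = 0.05,
                            warn_threshold = 0.9, switch_threshold = 1.0,
                            euthymic = NULL) {
  stopifnot(inherits(spec, "window_spec"), alpha > 0, alpha < 1)
  structure(list(spec = spec, lag = as.integer(lag), alpha = alpha,
                 warn_threshold = warn_threshold,
                 switch_threshold = switch_threshold, euthymic = euthymic),
            class = "bdews_config")
}

indicator_names <- function(lag) c("variance", "kurtosis", paste0("acf", lag))

#' Full per-patient early-warning analysis
#'
#' Runs the whole pipeline for one patient: episode-onset detection from the
#' weekly symptom scores, global linear detrending of the minute-level
#' counts, rolling 7-day/1-day windows, the three early-warning indicator
#' series, Mann-Kendall trend tests restricted to the four-week pre-onset
#' span, the rolling harmonic-ratio series with rhythm-transition events
#' (computed on raw counts), and the mean-activity comparisons of the
#' pre-onset and first-episode weeks against the euthymic reference week.
#'
#' @param activity An [activity_series()] of raw counts.
#' @param symptoms A [symptom_series()] covering the same period; its first
#'   week is aligned to the activity start.
#' @param config An [analysis_config()].
#' @return An object of class `patient_report`: list with `patient_id`,
#'   `episode_type`, `onset_day`, `trend` (data frame of exactly one row per
#'   indicator: `indicator`, `S`, `z`, `tau`, `n`, `p`, `sig`, `direction`,
#'   `testable`), `events`, `ratio_series`, `ews_series`, `intervals`,
#'   `activity_comparison` (pre-onset and during-episode labels), and
#'   `no_transition` when the symptom criteria never trigger (such patients
#'   are excluded from trend testing).
#' @export
analyze_patient <- function(activity, symptoms, config = analysis_config()) {
  stopifnot(inherits(activity, "activity_series"),
            inherits(symptoms, "symptom_series"),
            inherits(config, "bdews_config"))
  n_days <- length(activity$counts) %/% 1440L
  inames <- indicator_names(config$lag)

  onset <- detect_episode_onset(symptoms)
  if (is.null(onset)) {
    return(structure(list(patient_id = activity$patient_id,
                          episode_type = NA_character_,
                          onset_day = NA_integer_, no_transition = TRUE,
                          trend = NULL, events = NULL, ratio_series = NULL,
                          ews_series = NULL, intervals = NULL,
                          activity_comparison = NULL),
                     class = "patient_report"))
  }
  # symptom weeks are indexed from the activity start
  offset_days <- as.integer(symptoms$week_start_dates[1L] -
                              as.Date(activity$start_time))
  onset$onset_day <- onset$onset_day + offset_days
  intervals <- analysis_intervals(onset, n_days, euthymic = config$euthymic,
                                  q = symptoms)

  ews <- rolling_ews(make_windows(detrend_linear(activity), config$spec),
                     lag = config$lag)
  pre <- ews[ews$end_day >= intervals$pre_onset[1L] &
               ews$end_day < intervals$pre_onset[2L], , drop = FALSE]
  trend_rows <- lapply(inames, function(ind) {
    vals <- pre[[ind]][pre$usable]
    if (sum(!is.na(vals)) < 3L) {
      return(data.frame(indicator = ind, S = NA_real_, z = NA_real_,
                        tau = NA_real_, n = sum(!is.na(vals)), p = NA_real_,
                        sig = "", direction = NA_character_,
                        testable = FALSE))
    }
    mk <- mann_kendall(vals)
    data.frame(indicator = ind, S = mk$S, z = mk$z, tau = mk$tau, n = mk$n,
               p = mk$p, sig = significance_label(mk$p),
               direction = mk$direction, testable = TRUE)
  })
  trend <- do.call(rbind, trend_rows)

  ratio_series <- rolling_harmonic_ratio(make_windows(activity, config$spec))
  events <- detect_rhythm_transition(ratio_series,
                                     warn_threshold = config$warn_threshold,
                                     switch_threshold = config$switch_threshold)

  comparison <- NULL
  if (!is.null(intervals$euthymic)) {
    eu <- intervals$euthymic
    ref <- interval_mean(activity, c(eu[1L], min(eu[1L] + 7L, eu[2L])))
    pre_mean <- interval_mean(activity,
                              c(max(0L, onset$onset_day - 7L), onset$onset_day))
    comparison <- list(pre_onset = compare_mean_activity(ref, pre_mean))
    if (onset$onset_day + 7L <= n_days) {
      during <- interval_mean(activity, c(onset$onset_day, onset$onset_day + 7L))
      comparison$during_episode <- compare_mean_activity(ref, during)
    }
  }

  structure(list(patient_id = activity$patient_id,
                 episode_type = onset$episode_type,
                 onset_day = onset$onset_day, no_transition = FALSE,
                 trend = trend, events = events, ratio_series = ratio_series,
                 ews_series = ews, intervals = intervals,
                 activity_comparison = comparison),
            class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> %s: ", x$patient_id))
  if (isTRUE(x$no_transition)) {
    cat("no mood transition detected; excluded from trend testing\n")
    return(invisible(x))
  }
  cat(sprintf("%s episode, onset day %d\n", x$episode_type, x$onset_day))
  print(x$trend[, c("indicator", "z", "tau", "n", "p", "sig", "direction")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$events) && nrow(x$events) > 0L) {
    cat("rhythm events:\n")
    print(x$events, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write the per-patient report tables
#'
#' Writes `patient_report.csv` (one row per indicator: id, episode_type,
#' indicator, z, tau, n, p, sig, direction), `ews_series.csv` and
#' `ratio_series.csv` (with an `event` column) into `dir`.
#'
#' @param report A `patient_report` from [analyze_patient()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_patient_report <- function(report, dir) {
  stopifnot(inherits(report, "patient_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (isTRUE(report$no_transition)) {
    utils::write.csv(data.frame(id = report$patient_id,
                                episode_type = "no transition"),
                     file.path(dir, "patient_report.csv"), row.names = FALSE)
    return(invisible(dir))
  }
  tab <- cbind(id = report$patient_id, episode_type = report$episode_type,
               report$trend[, c("indicator", "z", "tau", "n", "p", "sig",
                                "direction")])
  utils::write.csv(tab, file.path(dir, "patient_report.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ews_series, file.path(dir, "ews_series.csv"),
                   row.names = FALSE)
  rs <- report$ratio_series
  rs$event <- ""
  if (nrow(report$events) > 0L) {
    rs$event[report$events$index] <- report$events$event
  }
  utils::write.csv(rs, file.path(dir, "ratio_series.csv"), row.names = FALSE)
  invisible(dir)
}

#' Group-level Fisher combination and significance counts
#'
#' Combines each indicator's per-patient p-values with [fisher_combine()]
#' and tallies how detection distributes over patients: how many have at
#' least one significant indicator, all three significant, and a significant
#' autocorrelation decrease or increase (direction from the sign of `S`,
#' i.e. of tau). Significance means `p <= alpha`, two-sided.
#'
#' @param reports Either a list of `patient_report` objects or a data frame
#'   with columns `id`, `indicator`, `p` and `tau` (e.g. a published
#'   per-patient results table).
#' @param alpha Significance level (default 0.05).
#' @param acf_indicator Name of the autocorrelation indicator row (default
#'   `"acf720"`).
#' @return An object of class `group_report`: list with `fisher` (named list
#'   of `fisher_combined`, one per indicator), `counts` (named integer
#'   vector: `any_significant`, `all_significant`, `acf_sig_decrease`,
#'   `acf_sig_increase`), `n_patients` and the per-patient long table used.
#' @export
combine_group <- function(reports, alpha = 0.05, acf_indicator = "acf720") {
  if (is.data.frame(reports)) {
    tab <- reports
  } else {
    rows <- lapply(reports, function(r) {
      stopifnot(inherits(r, "patient_report"))
      if (isTRUE(r$no_transition)) return(NULL)
      tr <- r$trend[r$trend$testable, , drop = FALSE]
      if (nrow(tr) == 0L) return(NULL)
      cbind(id = r$patient_id, tr[, c("indicator", "p", "tau")])
    })
    tab <- do.call(rbind, rows)
  }
  if (is.null(tab) || nrow(tab) == 0L) stop("no testable indicator rows")
  stopifnot(all(c("id", "indicator", "p", "tau") %in% names(tab)))
  tab <- tab[!is.na(tab$p), , drop = FALSE]
  fisher <- lapply(split(tab$p, tab$indicator), fisher_combine)
  sig <- tab$p <= alpha
  by_id <- split(data.frame(sig = sig, tau = tab$tau,
                            indicator = tab$indicator), tab$id)
  n_ind <- length(unique(tab$indicator))
  counts <- c(
    any_significant = sum(vapply(by_id, function(d) any(d$sig), logical(1))),
    all_significant = sum(vapply(by_id, function(d) {
      nrow(d) == n_ind && all(d$sig)
    }, logical(1))),
    acf_sig_decrease = sum(sig & tab$indicator == acf_indicator & tab$tau < 0),
    acf_sig_increase = sum(sig & tab$indicator == acf_indicator & tab$tau > 0)
  )
  structure(list(fisher = fisher, counts = counts,
                 n_patients = length(by_id), table = tab, alpha = alpha),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("<group_report> %d patients, alpha = %g\n", x$n_patients,
              x$alpha))
  for (ind in names(x$fisher)) {
    f <- x$fisher[[ind]]
    cat(sprintf("  %-10s combined p = %.4g (chi2 = %.2f, df = %d)\n",
                ind, f$p, f$chi2, f$df))
  }
  cat(sprintf("  >=1 significant: %d | all significant: %d | acf decrease: %d | acf increase: %d\n",
              x$counts["any_significant"], x$counts["all_significant"],
              x$counts["acf_sig_decrease"], x$counts["acf_sig_increase"]))
  invisible(x)
}

#' Reference per-patient trend-test outcomes
#'
#' Per-patient Mann-Kendall outcomes (z, tau, n, p, direction) for the three
#' early-warning indicators from a published eight-patient actigraphy study
#' of mood transitions in bipolar disorder type I, shipped as a plain-text
#' table. p-values printed there as "< 0.001" are stored at the censoring
#' bound 0.001. Useful as input to [combine_group()] and for checking the
#' tau-to-z relation of [mann_kendall_stats()].
#'
#' @return Data frame with columns `id`, `episode_type`, `indicator`, `z`,
#'   `tau`, `n`, `p`, `direction`.
#' @export
load_reference_trends <- function() {
  utils::read.csv(system.file("extdata", "reference_trend_tests.csv",
                              package = "bdews"),
                  stringsAsFactors = FALSE)
}

#' Reference mean-activity comparisons
#'
#' Seven-day mean activity levels (MotionWatch count units) from the same
#' published eight-patient study as [load_reference_trends()]: the euthymic
#' reference week against either the week immediately before episode onset
#' (`period = "pre_onset"`) or the first week of the episode
#' (`period = "during_episode"`).
#'
#' @param period Which comparison table to load.
#' @return Data frame with columns `id`, `episode_type`, `mean_euthymic`,
#'   `mean_episode`, `interpretation`.
#' @export
load_reference_activity <- function(period = c("pre_onset", "during_episode")) {
  period <- match.arg(period)
  f <- if (period == "pre_onset") "reference_mean_activity_pre.csv"
       else "reference_mean_activity_during.csv"
  utils::read.csv(system.file("extdata", f, package = "bdews"),
                  stringsAsFactors = FALSE)
}
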