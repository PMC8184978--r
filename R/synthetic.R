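# Run expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parameters of the synthetic circadian activity generator
#'
#' Defines a cosinor mean curve (mesor + amplitude x 24-h cosine, trough at
#' midnight, peak at noon) with additive Gaussian epoch noise truncated at
#' zero — the simplest process with the day/night contrast, heteroscedastic
#' non-negative counts and dominant 24-h spectral peak that wrist actigraphy
#' exhibits. Defaults emulate a six-month continuous recording at count
#' levels typical of wrist-worn devices, with the noise scale at one quarter
#' of the amplitude so the 24-h rhythm clearly dominates.
#'
#' @param n_days Recording length in days (>= 8 so at least two rolling
#'   windows exist); default 180.
#' @param mesor Baseline count level (default 100 count units).
#' @param amplitude 24-h cosine amplitude in count units (default 100, so
#'   the mean curve spans 0 at night to 200 at midday).
#' @param noise_sd Epoch noise standard deviation in count units
#'   (default 25).
#' @param seed Integer random seed; identical parameters and seed give a
#'   bit-identical series.
#' @param start_time Timestamp of the first epoch (default midnight,
#'   2020-01-06, a Monday).
#' @return An object of class `circadian_params`.
#' @export
circadian_params <- function(n_days = 180L, mesor = 100, amplitude = 100,
                             noise_sd = 25, seed = 1L,
                             start_time = as.POSIXct("2020-01-06 00:00:00",
                                                     tz = "UTC")) {
  n_days <- as.integer(n_days)
  if (n_days < 8L) stop("n_days must be at least 8")
  if (amplitude < 0 || noise_sd < 0) stop("amplitude and noise_sd must be >= 0")
  if (mesor < 0) stop("mesor must be >= 0")
  structure(list(n_days = n_days, mesor = mesor, amplitude = amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 start_time = start_time),
            class = "circadian_params")
}

#' Pre-transition signature specification
#'
#' Describes the signature injected before a synthetic mood-episode onset:
#' a linear ramp of the epoch noise standard deviation from `noise_sd` up to
#' `noise_sd * variance_gain` over the `ramp_days` preceding onset (the
#' monotone-trend alternative the Mann-Kendall test targets; the scale stays
#' at the ramp top from onset onward), and optionally a circadian rhythm
#' switch that replaces the 24-h cosine by one of period `switch_period`
#' minutes (same amplitude) from `switch_day` onward, reproducing the
#' deregulation from a 24-h to e.g. a 12-h or 4-h rhythm.
#'
#' @param onset_day 0-based day index of the episode onset.
#' @param ramp_days Length of the pre-onset noise ramp in days (default 28).
#' @param variance_gain Multiplicative factor on the noise sd reached at
#'   onset (default 4; 1 means no ramp).
#' @param episode_type "manic" or "depressive".
#' @param switch_period Optional target period in minutes (e.g. 720).
#' @param switch_day 0-based day the rhythm switch takes effect; required
#'   with `switch_period`.
#' @return An object of class `transition_spec`.
#' @export
transition_spec <- function(onset_day, ramp_days = 28L, variance_gain = 4,
                            episode_type = c("depressive", "manic"),
                            switch_period = NULL, switch_day = NULL) {
  episode_type <- match.arg(episode_type)
  onset_day <- as.integer(onset_day)
  ramp_days <- as.integer(ramp_days)
  if (ramp_days < 1L) stop("ramp_days must be at least 1")
  if (ramp_days > onset_day) stop("ramp would extend before day 0")
  if (variance_gain <= 0) stop("variance_gain must be positive")
  if (!is.null(switch_period) && is.null(switch_day)) {
    stop("switch_day is required when switch_period is set")
  }
  structure(list(onset_day = onset_day, ramp_days = ramp_days,
                 variance_gain = variance_gain, episode_type = episode_type,
                 switch_period = if (is.null(switch_period)) NULL
                                 else as.integer(switch_period),
                 switch_day = if (is.null(switch_day)) NULL
                              else as.integer(switch_day)),
            class = "transition_spec")
}

# Deterministic synthesis shared by the generator and the injector: same
# params + seed give the same standard-normal draws, so a spec that changes
# nothing reproduces the original series exactly.
synth_counts <- function(params, spec = NULL) {
  n <- params$n_days * 1440L
  eps <- with_local_seed(params$seed, stats::rnorm(n))
  t_min <- as.numeric(seq_len(n) - 1L)
  period <- rep(1440, n)
  if (!is.null(spec) && !is.null(spec$switch_period)) {
    period[t_min >= spec$switch_day * 1440] <- spec$switch_period
  }
  mu <- params$mesor + params$amplitude * cos(2 * pi * (t_min - 720) / period)
  sd_t <- rep(params$noise_sd, n)
  if (!is.null(spec) && spec$variance_gain != 1) {
    ramp_start <- (spec$onset_day - spec$ramp_days) * 1440
    onset <- spec$onset_day * 1440
    frac <- pmin(1, pmax(0, (t_min - ramp_start) / (onset - ramp_start)))
    sd_t <- params$noise_sd * (1 + (spec$variance_gain - 1) * frac)
  }
  pmax(0, mu + sd_t * eps)
}

#' Generate a synthetic circadian activity series
#'
#' @param params A [circadian_params()].
#' @return An [activity_series()] of `n_days * 1440` one-minute epochs, all
#'   observed, with the generation parameters attached (used by
#'   [inject_transition_signature()]).
#' @export
generate_circadian_series <- function(params = circadian_params()) {
  stopifnot(inherits(params, "circadian_params"))
  out <- activity_series(synth_counts(params), start_time = params$start_time,
                         patient_id = sprintf("sim-%d", params$seed))
  attr(out, "circadian_params") <- params
  out
}

#' Inject a pre-transition signature into a synthetic series
#'
#' Re-synthesises the series from its stored generation parameters with the
#' signature applied: counts before the ramp (and before any rhythm switch)
#' are bit-identical to the input, the epoch noise scale rises linearly to
#' `noise_sd * variance_gain` at onset, and the periodic component changes
#' period from `switch_day` onward when a switch is specified. Output counts
#' remain non-negative. Only series produced by
#' [generate_circadian_series()] carry the parameters this needs.
#'
#' @param series An [activity_series()] from [generate_circadian_series()].
#' @param spec A [transition_spec()].
#' @return An [activity_series()] with the signature applied; the spec is
#'   attached as attribute `transition_spec`.
#' @export
inject_transition_signature <- function(series, spec) {
  stopifnot(inherits(series, "activity_series"),
            inherits(spec, "transition_spec"))
  params <- attr(series, "circadian_params")
  if (is.null(params)) {
    stop("series carries no generation parameters; only output of generate_circadian_series can be re-synthesised")
  }
  if (spec$onset_day > params$n_days) stop("onset_day lies outside the series")
  if (!is.null(spec$switch_day) && spec$switch_day > params$n_days) {
    stop("switch_day lies outside the series")
  }
  out <- activity_series(synth_counts(params, spec),
                         start_time = params$start_time,
                         patient_id = series$patient_id)
  attr(out, "circadian_params") <- params
  attr(out, "transition_spec") <- spec
  out
}

#' Generate a weekly symptom series with a known episode
#'
#' Baseline weeks draw ASRM from 0-3 and IDS-SR from 8-20, so neither
#' episode criterion can trigger spuriously. When an episode is specified,
#' the relevant score is elevated from the onset week (`onset_day %/% 7`)
#' through the end of the series: ASRM in 7-14 for manic episodes (criterion:
#' > 5 for 2 consecutive weeks), IDS-SR in 28-45 for depressive episodes
#' (criterion: > 25 for 3 consecutive weeks).
#'
#' @param n_weeks Number of weekly assessments.
#' @param episode Optional [transition_spec()]; its `onset_day` and
#'   `episode_type` place the episode. `NULL` for a fully euthymic series.
#' @param seed Integer random seed.
#' @param start_date Date of the first assessment week (default 2020-01-06,
#'   matching the activity generator's start).
#' @param patient_id Label for the series.
#' @return A [symptom_series()].
#' @export
generate_symptom_series <- function(n_weeks, episode = NULL, seed = 1L,
                                    start_date = as.Date("2020-01-06"),
                                    patient_id = "synthetic") {
  n_weeks <- as.integer(n_weeks)
  if (n_weeks < 2L) stop("n_weeks must be at least 2")
  scores <- with_local_seed(seed, {
    list(asrm = sample(0:3, n_weeks, replace = TRUE),
         ids = sample(8:20, n_weeks, replace = TRUE),
         hi_asrm = sample(7:14, n_weeks, replace = TRUE),
         hi_ids = sample(28:45, n_weeks, replace = TRUE))
  })
  asrm <- scores$asrm
  ids <- scores$ids
  if (!is.null(episode)) {
    stopifnot(inherits(episode, "transition_spec"))
    w <- episode$onset_day %/% 7L  # 0-based onset week
    need <- if (episode$episode_type == "manic") 2L else 3L
    if (w + need > n_weeks) {
      stop("episode onset week leaves too few weeks to satisfy the criterion")
    }
    idx <- (w + 1L):n_weeks
    if (episode$episode_type == "manic") {
      asrm[idx] <- scores$hi_asrm[idx]
    } else {
      ids[idx] <- scores$hi_ids[idx]
    }
  }
  symptom_series(start_date + 7L * (seq_len(n_weeks) - 1L), asrm, ids,
                 patient_id = patient_id)
}

#' Simulate one synthetic patient
#'
#' Convenience wrapper producing matched activity and symptom series plus
#' the ground truth needed to score detection: activity from
#' [generate_circadian_series()] with the signature of `spec` injected, and
#' symptoms from [generate_symptom_series()] with the episode placed at the
#' same onset.
#'
#' @param params A [circadian_params()].
#' @param spec Optional [transition_spec()]; `NULL` simulates a euthymic
#'   (null) patient.
#' @return List with elements `activity`, `symptoms` and `truth` (onset day,
#'   episode type, switch day and period, seed).
#' @export
simulate_patient <- function(params = circadian_params(), spec = NULL) {
  activity <- generate_circadian_series(params)
  if (!is.null(spec)) activity <- inject_transition_signature(activity, spec)
  symptoms <- generate_symptom_series(params$n_days %/% 7L, episode = spec,
                                      seed = params$seed + 10007L,
                                      start_date = as.Date(params$start_time),
                                      patient_id = activity$patient_id)
  truth <- list(seed = params$seed,
                onset_day = if (is.null(spec)) NA_integer_ else spec$onset_day,
                episode_type = if (is.null(spec)) NA_character_
                               else spec$episode_type,
                switch_day = if (is.null(spec) || is.null(spec$switch_day))
                               NA_integer_ else spec$switch_day,
                switch_period = if (is.null(spec) || is.null(spec$switch_period))
                                  NA_integer_ else spec$switch_period)
  list(activity = activity, symptoms = symptoms, truth = truth)
}
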