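# Shared fixture builders; all fixtures are constructed in code.

t0 <- as.POSIXct("2020-01-06 00:00:00", tz = "UTC")

# Pure sinusoid activity series (non-negative: offset above amplitude).
sinusoid_series <- function(n_days = 7, period = 1440, amplitude = 1,
                            offset = 2) {
  t_min <- 0:(n_days * 1440 - 1)
  activity_series(offset + amplitude * sin(2 * pi * t_min / period),
                  start_time = t0, patient_id = "sine")
}

# Weekly symptom series from raw score vectors.
weeks_series <- function(asrm, ids_sr = rep(10L, length(asrm))) {
  symptom_series(as.Date("2020-01-06") + 7 * (seq_along(asrm) - 1),
                 asrm, ids_sr)
}

# Brute-force Mann-Kendall S and tau by explicit double loop (independent
# oracle for the pairwise-sign statistic).
mk_brute_force <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  S <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[j] - x[i])
    }
  }
  list(S = S, tau = S / (n * (n - 1) / 2))
}
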