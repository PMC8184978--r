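Package: bdews
Title: Early-Warning Signals and Spectral Periodicity for Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rolling-window early-warning-signal analysis of minute-epoch
    actigraphy for anticipating mood-episode transitions in bipolar
    disorder. Computes variance, Pearson kurtosis and lag-720
    autocorrelation over sliding 7-day windows, tests pre-onset monotonic
    trends with the ties-corrected Mann-Kendall test, combines per-patient
    p-values with Fisher's method, and tracks circadian rhythm stability
    through unsmoothed FFT periodograms and the second-harmonic to
    fundamental power ratio. Episode onsets are derived from weekly ASRM
    and IDS-SR symptom scores. A seeded synthetic actigraphy and symptom
    generator with injectable pre-transition signatures (variance ramps,
    24-h to 12-h rhythm switches) supports calibration and power studies
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
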