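Package: ipipredict
Title: Predictability of EEG Inter-Peak-Interval Dynamics Across Sleep States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the predictability of single-channel EEG dynamics by
    extracting inter-peak intervals (IPI) from the Gaussian-smoothed signal and
    forecasting each interval one step ahead with a small feed-forward neural
    network trained by the Levenberg-Marquardt algorithm. Provides readers for
    EDF and plain-text traces, peak and IPI extraction, chronological windowed
    train/validation/test splits, effect-size statistics (Welch t-test and
    Cohen's d on log-transformed absolute errors, moment skewness), Welch power
    spectra with alpha-band summaries, and a three-state synthetic EEG generator
    with autoregressive, positively skewed interval structure so the whole
    pipeline is testable end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
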