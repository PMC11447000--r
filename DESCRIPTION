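Package: neuromark
Title: Quantitative EEG and HD-MEA Biomarkers for Rodent Neurophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for neurophysiological biomarkers of cortical
    hyperexcitability in rodent models of neurodevelopmental disorders.
    Computes Hamming-windowed power spectral densities and canonical band
    powers from telemetric EEG, detects epileptiform spikes and chains them
    into spike trains under amplitude/duration/interval rules, scores sleep
    into four stages (active wake, wake, slow-wave sleep, paradoxical sleep)
    from delta-, theta:delta- and EMG-ratio membership functions plus an
    accelerometer override, and quantifies network bursts on high-density
    microelectrode array recordings via Gaussian-smoothed population firing
    rates. Ships seeded synthetic-signal generators with ground truth for
    every stage, plus Grubbs outlier screening and pooled two-group t-tests
    for cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
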