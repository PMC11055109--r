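Package: eegfatigue
Title: EEG Band-Power Ratio Analysis of Driving Fatigue and Scent
    Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying driver fatigue from temporal-lobe EEG.
    Implements classical direct-method (periodogram) spectral estimation,
    band-average power spectral density for the theta, alpha, beta and
    gamma bands, and the ratio indices R(alpha/beta), R(theta/(alpha+beta))
    and R((alpha+theta)/(alpha+beta)) that rise as drivers tire.  Provides
    the two standard study pipelines built on these indices: a fatigue
    identification study (paired contrasts of early- versus late-drive
    index values together with Karolinska Sleepiness Scale scores) and a
    scent intervention study (per-minute alpha/beta trajectories around a
    timed odor release, paired baseline contrasts and two-way
    repeated-measures ANOVA).  A calibrated synthetic EEG and KSS
    generator emulates the fatigue drift and scent-rebound dynamics these
    analyses assume, so the full pipeline is testable without access to
    raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
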