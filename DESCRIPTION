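Package: vsdtrace
Title: Slope-Based Salient-Point Analysis of Optical Neuro-Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts salient activity-pattern features (maximum and minimum
    slope points, activity-plateau begin and end points) from noisy optical
    imaging traces of rhythmically bursting neurons using sliding-window
    least-squares slope estimation, and quantifies the dynamics of temporal
    relationships between neurons (phase locking and de-synchronisation)
    via matched temporal-delay statistics and F-test variance comparisons.
    Includes the analytic noise model for the slope estimator, a synthetic
    trace generator with exact ground truth, event-triggered averaging,
    delimited-text trace I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
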