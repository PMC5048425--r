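Package: circapulse
Title: Circadian Entrainment to Randomly Timed Single Daily Light Pulses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for photic entrainment of
    circadian rhythms under irregular light/dark schedules. Generates
    light regimens consisting of one brief light pulse per day at random
    times within a daytime dispersion window, simulates a limit-cycle
    circadian oscillator with photic forcing, synthesises wheel-running
    activity records and field light-logger records, and provides the
    standard rhythm analyses: chi-square periodogram, entrainment
    classification, activity phase markers (onset, offset, centre of
    gravity), phase dispersion, side-band detection, actograms, and
    light-exposure episode statistics with civil-twilight checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
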