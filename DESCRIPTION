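Package: clockamp
Title: Amplitude Response of Coupled Circadian Limit-Cycle Oscillators to Light Pulses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the amplitude response of circadian clocks to light
    pulses using a planar normal-form (Poincare) limit-cycle oscillator and
    heterogeneous populations of such oscillators coupled through a
    saturating mean field. Light acts either by transcriptional activation
    (a push on the mRNA coordinate) or by protein degradation (a push on the
    protein coordinate), or by both at once. The package provides the
    geometric circadian-time conventions, calibration of the limit-cycle
    radius against the critical (singularity-inducing) pulse, four
    before/after response indices (single-cell amplitude ratio, average
    amplitude ratio, mean individual amplitude ratio, and a Kuramoto
    order-parameter synchronization ratio), phase-shift measurement against
    an unstimulated control, and scan experiments over stimulus phase and
    strength: amplitude response curves and surfaces, singularity
    localization, monotonicity classification, amplitude-reduction phase
    ranges, and combined-stimulus strategies for resetting phase without
    losing amplitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
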