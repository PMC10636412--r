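Package: infasym
Title: Infant Frontal Alpha Asymmetry from Mother-Infant Interaction EEG
Version: 0.1.0
Authors@R:
    person("Maya", "Kovac", email = "maya.kovac@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of infant EEG recorded during a structured
    mother-infant multisensory interaction. Preprocesses high-density
    recordings (notch and Butterworth band-pass filtering, average
    re-referencing, bad-channel interpolation, amplitude-artifact
    elimination), extracts the infant alpha band (6-9 Hz) over seven-electrode
    clusters around F3 and F4, computes Hilbert envelopes and alpha-band
    global field power, aligns repeated action iterations by cross-correlation
    of global field power, and derives per-action frontal asymmetry scores
    FAS = (F3 - F4)/(F3 + F4) with action-1 baseline subtraction. Aggregates
    Welch Emotional Connection Scale behavioral codes, classifies infant
    irritability and maternal bondedness, and provides the trend, correlation
    and group-interaction statistics used with such designs. Includes a
    synthetic dyad-session generator with known ground truth (lateralized
    alpha bursts, onset jitter, blink-like artifacts, bad channels) so the
    whole pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
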