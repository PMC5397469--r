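Package: ictomap
Title: Spatiotemporal Mapping of Epileptiform Discharges in Multi-Electrode
    Array Slice Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 60-channel micro-electrode array (MEA)
    recordings of epileptiform activity in hippocampal slices. Converts raw
    wide-band recordings to field potentials (zero-phase 1-100 Hz band-pass,
    decimation to 1 kHz), detects per-electrode epileptiform events against a
    baseline-referenced threshold (4 x SD of a quiescent 500 ms window),
    groups events into network discharges, classifies them as interictal-like
    (IID) or ictal-like (ID) by a 5 s duration cutoff, localizes initiation
    sites (CA3a/b versus subiculum) from relative onset-time delay maps,
    segments recurring discharge cycles (IID train + one ID + resting period),
    and compares per-region event parameters across drug epochs. Ships a
    synthetic slice-recording simulator with ground truth for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
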