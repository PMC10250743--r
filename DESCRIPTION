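Package: texeeg
Title: Characterization Pipeline for Textile and Dry Forehead EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for benchmarking a textile (garment) EEG
    sensor layer against a metal dry-electrode baseline on a four-channel
    forehead montage (F7, Fp1, Fp2, F8 at 256 Hz). Implements the full
    study workflow: zero-phase Butterworth filtering, Hilbert-envelope
    amplitude-outlier removal, Welch power spectral density with band-power
    summaries, Morlet-wavelet time-frequency maps with event-related
    (de)synchronization (ERD/ERS) baselining, bin-wise and band-wise paired
    Wilcoxon signed-rank comparisons with exact enumeration, Cole-model
    skin-electrode impedance calibration and simulation, plus a seeded
    synthetic-session generator (resting state, cued reaching, artifact
    induction) so every stage is testable without external recordings.
    EDF and CSV readers/writers are included for interoperability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
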