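Package: moveintent
Title: Continuous Detection of Upper-Limb Movement Intention from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the intention to move the upper limbs from
    electroencephalographic (EEG) recordings of self-paced reaching
    movements. Implements EMG-based labelling of movement onset via a
    Hilbert envelope, trial screening and onset re-referencing, standard
    EEG preprocessing (channel selection, anti-aliased resampling,
    zero-phase band-pass filtering, common average reference),
    time-frequency maps of event-related desynchronization and
    synchronization (ERD/ERS) with trial-level bootstrap significance,
    causal Burg autoregressive spectral-power features, and continuous
    sliding-window detection of relax versus movement intention with a
    radial-basis-function support vector machine, permutation-based
    empirical chance levels and time-resolved detection metrics. A
    synthetic EEG/EMG session generator with known ground truth supports
    calibration and parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
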