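Package: emgsynergy
Title: Muscle Synergy Extraction and Similarity Analysis for Cyclic EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-muscle surface electromyography (EMG)
    recorded during cyclic motor tasks. Implements the standard envelope
    preprocessing chain (band-pass filtering, rectification, zero-lag low-pass
    smoothing, cycle time-normalisation and amplitude normalisation),
    non-negative matrix factorization with Lee-Seung multiplicative updates and
    a multi-restart protocol, variance-accounted-for (VAF) diagnostics at the
    total, per-muscle and per-synergy level, three synergy-number selection
    criteria (VAF threshold, best linear fit, knee point against shuffled
    surrogates), fixed-vector and fixed-coefficient cross-validation across
    recording sets and subjects, waveform similarity statistics (Pearson r,
    circular cross-correlation, lag), permutation null distributions for
    synergy-vector similarity, and planar multi-segment biomechanics (moment of
    inertia and mass-normalised mechanical energy of a swinging body). A
    synthetic-data module generates EMG cohorts with known ground-truth
    synergies and planar giant-swing marker trajectories so that every stage of
    the analysis can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
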