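Package: hdssvep
Title: High-Density EEG Decoding for Frequency-Phase-Space SSVEP
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating steady-state visual evoked
    potential (SSVEP) brain-computer interfaces that encode targets jointly by
    stimulus frequency, phase and fixation position. Provides the hybrid
    frequency-phase-space code table and stimulus layout, idealized
    high-density parieto-occipital electrode montages (66/256, 32/128, 21/64
    and 9/64 configurations), a seeded generator of synthetic SSVEP epochs
    with fixation-dependent amplitude and phase topographies and spatially
    correlated 1/f background noise, filter-bank task-discriminant component
    analysis (TDCA) and task-related component analysis (TRCA) decoders,
    confidence-weighted dynamic-window classification, information transfer
    rate and narrow-band signal-to-noise metrics, leave-one-block-out
    cross-validation, greedy backward electrode selection, and a small
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
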