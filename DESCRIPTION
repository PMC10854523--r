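Package: pacnav
Title: Phase-Amplitude Coupling Analysis for Hippocampal Recordings During
    Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies cross-frequency coupling between the phase of slow
    (theta-band) oscillations and the amplitude envelope of faster
    oscillations in local field potential recordings, using the
    Kullback-Leibler based modulation index of Tort and colleagues.
    Provides zero-phase band filtering and analytic-signal phase/envelope
    extraction, comodulograms over phase-by-amplitude frequency grids,
    cross-trial phase-amplitude distribution correlation, circular-shift
    surrogate nulls, circular statistics (mean resultant vector, Rayleigh
    test), behavioural segmentation of maze sessions (event-locked epochs)
    and homing-flight GPS tracks (decision-making / en-route / local
    navigation phases, path similarity), nonparametric group comparisons
    (Kruskal-Wallis with Dunn's post hoc, Mann-Whitney U, Spearman), and a
    seeded synthetic-data generator for LFPs with controllable coupling,
    maze event streams, and flight tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    signal,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
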