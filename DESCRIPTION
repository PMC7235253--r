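Package: hippotheta
Title: Narrowband Theta Oscillation Detection and Hippocampal
    Anterior-Posterior Gradient Analysis for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects narrowband 2-14 Hz oscillations in intracranial EEG
    over the 1/f background spectrum, derives band-limited instantaneous
    frequency, phase and presence masks, classifies hippocampal electrodes
    as single or dual theta oscillators along the anterior-posterior axis,
    quantifies oscillatory bout durations in cycles, and tests whether
    high-theta frequency tracks virtual-movement speed.  Includes a seeded
    synthetic-cohort generator (1/f LFP with embedded oscillatory bouts,
    anatomical frequency gradients, speed-coupled frequency modulation and
    a constant-speed-epoch virtual navigation task) plus group-level
    prevalence, gradient, hemisphere, harmonic and co-occurrence
    statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
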