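Package: phasecoord
Title: Phase-Coherence Coordination Dynamics for Multichannel Brain Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic functional-coordination analysis of multichannel brain
    time series. Extracts instantaneous phases from band-limited regional
    signals via the analytic (Hilbert) representation, builds per-timepoint
    phase-coherence matrices, discovers recurrent whole-brain coordination
    patterns with k-means clustering (inter-pattern correlation variance and
    elbow diagnostics for choosing the number of patterns), ranks patterns by
    their correlation with a structural connectome, and quantifies dynamics
    through pattern occupancy rates, Shannon entropy, occupancy-versus-
    structure slopes, and Markov transition matrices tested against a
    temporal-shuffle permutation null. A synthetic-data generator produces
    state-switching narrowband regional signals with planted coherence
    templates so the full pipeline can be exercised and calibrated without
    access to raw imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
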