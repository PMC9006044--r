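Package: neofc
Title: Resting-State Functional Connectivity of High-Order Brain Networks in Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional-connectivity (FC)
    analysis of the three high-order brain networks (default mode, dorsal
    attention, executive control) in neonatal fMRI: DVARS-based motion-outlier
    detection and continuous-window scrubbing, sphere-ROI time-course
    extraction from 4D volumes, zero-phase temporal low-pass filtering,
    Fisher-z FC matrices with within-subject normalization and network-level
    summaries, repeated-measures ANOVA with Greenhouse-Geisser sphericity
    correction, motion-adjusted group comparisons, verdict procedures for
    network distinctness and the default-mode/dorsal-attention reciprocal
    relationship, and node-level network-structure analysis via hierarchical
    clustering and non-metric multidimensional scaling. A synthetic BOLD
    cohort generator with known block covariance, temporal autocorrelation,
    motion spikes, and configurable group profiles makes every stage
    verifiable without access to restricted infant imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    RNifti,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
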