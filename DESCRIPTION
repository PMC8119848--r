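Package: restnet
Title: Resting-State EEG Band Power, Envelope Connectivity and Network Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state EEG group studies: epoching,
    artifact channel/epoch rejection, hemisphere flipping, common-average
    re-referencing and 5-Hz band separation; Welch band power with impedance-free
    normalization and electrode directional asymmetry; atlas reduction and
    PCA region time courses; leakage-corrected (symmetrically orthogonalized)
    amplitude-envelope correlation connectivity with phase-randomization
    surrogate bias normalization and connectivity asymmetry; network-based
    statistic permutation inference; and a group-level battery (mixed ANOVA
    with sphericity handling, Holm-Sidak, bootstrap Tukey, clinical-score
    regression). Includes a synthetic cohort generator with planted effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
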