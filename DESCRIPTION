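Package: tgdecode
Title: Temporal Generalization Decoding of Overlapping Responses in Rapid
    Visual Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and decoding toolkit for rapid serial visual
    presentation (RSVP) experiments in which evoked sensor-level responses
    to successive stimuli overlap in time. Provides a forward simulator of
    multi-sensor localizer and dual-task RSVP recordings with known
    category-specific spatiotemporal response stages and configurable
    attentional-selection models (gradual graded amplification versus
    discrete all-or-none gating of reported stimuli), per-timepoint
    one-vs-rest linear support-vector decoding with probabilistic output
    and leakage-free cross-validated temporal generalization,
    localizer-to-stream classifier transfer with per-stimulus realignment,
    projection of classifier weights into interpretable activation
    patterns, behavioral report-distribution analyses, and the matching
    statistical layer (exact Wilcoxon signed-rank tests, Benjamini-Hochberg
    false-discovery-rate families, and repeated-measures ANOVA on
    aligned-rank-transformed data).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
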