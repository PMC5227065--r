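Package: lamflow
Title: Laminar Electrophysiology Pipeline for Attention and Working-Memory
    Modulation in Early Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured multi-contact laminar
    probe recordings from primary visual cortex: multi-unit activity (MUA)
    envelope extraction, one-dimensional current-source density (CSD)
    estimation, depth alignment of penetrations by the layer-4C/5 CSD
    polarity reversal, laminar compartment assignment, response
    normalization and latency fits, attention/working-memory modulation
    profiles, penetration-level nonparametric tests, repeated-measures
    ANOVA with Greenhouse-Geisser correction, laminar-profile consistency
    correlations with shuffle controls, cluster-based sign-flip
    permutation tests, single-trial SVM/ROC decoding, and microsaccade
    screening of eye traces.  Includes a synthetic laminar-column
    generator with known ground truth (layered sink/source CSD profiles,
    per-layer latencies, condition-dependent sustained modulation, mask
    transients) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
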