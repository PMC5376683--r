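Package: scfib
Title: Single-Cell qPCR Profiling of Fibroblast Activation States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput single-cell RT-qPCR panels of
    fibroblasts and cancer-associated fibroblasts (CAFs). Converts quantification
    cycles (Cq) to relative quantities, applies GAPDH-based quality gating and the
    log2 / autoscaling / mean-centering conventions used in single-cell qPCR work,
    discovers subpopulations by Spearman correlation clustering and self-organizing
    maps, quantifies per-group detection frequency and expression level, detects
    bimodal marker expression with a two-component Gaussian mixture, builds a
    pseudo-temporal differentiation model (frequency times expression per state)
    with marker-rule state labelling, and classifies new cells by projection into
    a reference principal-component space with nearest-centroid assignment. Ships
    a synthetic plate generator with planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
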