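Package: refstab
Title: Reference-Gene Stability Analysis for qRT-PCR of Complex Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting and validating qRT-PCR reference genes in
    complex, developing tissues. Mines candidate reference genes from grouped
    log2 expression matrices by log-fold-change window intersection, scores
    candidates with four stability algorithms (GeNorm M-values with stepwise
    exclusion and pairwise variation, comparative DeltaCt, BestKeeper,
    NormFinder), aggregates rankings by the geometric mean of per-algorithm
    positions, and quantifies target genes by the efficiency-corrected
    comparative delta-Ct method against a multi-gene normalization factor.
    Includes a seeded simulator of Ct tables and expression matrices with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
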