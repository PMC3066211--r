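Package: kinscreen
Title: Dual-Channel Arrayed RNAi Screen Analysis with Robust Z-Scores and
    siRNA Concordance Hit Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of arrayed dual-channel RNAi screens in 96-well plates,
    as used for kinome-wide screens that read out a reporter enzyme activity
    (EROD, kinetic fluorescence slope) alongside a cell-density channel
    (methylene blue absorbance). Provides plate-median and control-percentage
    normalization, per-well activity/density ratios with a viability validity
    floor, per-replicate robust z-scores (median/MAD), replicate summarization
    and QC (pairwise replicate correlation, quantile-quantile and plate-image
    exports), gene-level hit calling by a top-k / at-least-m-of-r siRNA
    concordance rule with a cell-density confound filter, hypergeometric
    term enrichment with Benjamini-Hochberg FDR and a floored coverage
    statistic, and a seeded synthetic-screen generator with known ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
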