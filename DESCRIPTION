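Package: omicomp
Title: Cross-Dataset Comparison of Differential Expression Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless engine for comparing differential-expression results
    across omics datasets: dataset ingestion and merging on shared feature
    IDs, cross-comparison feature classification (shared, contra, unique),
    Venn and UpSet exclusive-intersection analytics with fold-direction
    splitting, a direction-concordance-by-p-value profile, presence/absence
    analysis of features below detection limit, per-feature cross-layer
    correlation, sample-level quality computations (PCA, average-linkage
    dendrograms, distribution summaries), Benjamini-Hochberg adjustment and
    a Welch two-group test, synthetic spike-in and multiomics generators,
    figure/table export, settings snapshots and static HTML reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
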