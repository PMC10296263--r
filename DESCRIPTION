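Package: anchorscope
Title: Anchor-Gene Transcriptome Context Analysis with Differential
    Ratio and Network Intermediary Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the transcriptomic context of a
    single anchor gene (such as RUNX3 in CD14+ monocytes) across two
    independent expression cohorts. Implements microarray-style
    preprocessing (median-expression filtering, offset plus log
    transform), transcriptome-wide Pearson correlation with
    Benjamini-Hochberg adjustment and cross-cohort mean-r meta-ranking,
    tuned extremely-randomized-forest feature selection with
    cross-cohort importance intersection, and DRAIMI (Differential
    Ratio Analysis with InterMediary Inference): bootstrap ranking of
    transcript ratios that differ between the upper and bottom anchor
    deciles, followed by scoring of pivot genes that interact with both
    members of a top ratio in a protein-protein interaction network.
    Includes a synthetic two-cohort data generator with planted
    correlates, differential ratio pairs and pivot nodes so every stage
    can be validated against a known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
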