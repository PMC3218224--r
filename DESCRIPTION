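Package: tempodeg
Title: Temporal Knockdown Transcriptome Analysis with Two-Way ANOVA,
    SOM Clustering and GO Overrepresentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differentially expressed genes in short time-course
    knockdown microarray experiments (two groups sampled on a few days)
    using two two-way ANOVA models -- an interaction test and an additive
    group-effect test -- with family-wise error control by Westfall-Young
    step-down maxT permutation adjustment, clusters the resulting temporal
    log2-ratio profiles on a small self-organizing map, selects early/late
    up/down gene-sets by an interquartile-box threshold rule, and tests the
    gene-sets for ontology-term overrepresentation (binomial or
    hypergeometric tails, Bonferroni or Benjamini-Hochberg correction)
    after evidence-code filtering and annotation propagation. Includes a
    synthetic-data generator with planted temporal archetypes and planted
    term enrichment for end-to-end validation, and a comparative-Ct
    (2^-ddCt) utility for qPCR follow-up.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
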