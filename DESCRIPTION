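Package: mirpath
Title: Integrative miRNA-mRNA Expression Analysis with Pathway Enrichment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for joint interpretation of miRNA and mRNA
    expression profiling in a time-course design. Two-channel miRNA array
    signals are background-corrected, normalized with cyclic loess, and
    summarized into per-miRNA fold inductions with one-sample t-tests.
    Differentially expressed miRNA and mRNA sets are constructed under
    fold-change and probe-consistency rules, crossed with target-prediction
    tables to yield inversely correlated miRNA-mRNA pairs, and pathway
    enrichment is scored by combining a permutation-based miRNA-target
    statistic with a hypergeometric mRNA statistic via Stouffer's method.
    Bench-assay arithmetic (delta-delta-Ct quantification, cross-platform
    concordance, reporter knockdown ratios) and a seeded synthetic-data
    generator with packaged reference fixtures support validation and
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
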