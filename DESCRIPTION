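Package: proteoMR
Title: Cis-pQTL Discovery and Two-Sample Mendelian Randomisation for
    Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline from affinity-proteomics (NPX) protein
    measurements to protein-disease causal estimates. Implements
    limit-of-detection based quality control of NPX matrices, per-protein
    association with clinical characteristics under global false-discovery
    control, cis-window protein quantitative trait locus (pQTL) scanning with
    per-region independent-variant multiple-testing correction, greedy LD
    clumping for instrument selection, exposure-outcome allele harmonisation,
    Wald-ratio and fixed-effect inverse-variance-weighted Mendelian
    randomisation against case-control GWAS summary statistics, discovery and
    replication screening, and regional mirror-plot concordance diagnostics.
    A synthetic-data generator produces LD-structured genotypes, cis-regulated
    NPX levels with censoring at the limit of detection, and case-control
    outcome summary statistics under null, causal and LD-confounded scenarios,
    so the whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
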