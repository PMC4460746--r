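Package: gwas2drug
Title: Drug Repositioning from GWAS Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for translating genome-wide association study (GWAS)
    results into drug-repositioning hypotheses. Association results are
    stratified into nested significance sets, gene search spaces are built
    around each SNP locus by fixed-width and k-nearest-gene rules, and five
    cross-locus candidate-gene heuristics (shared pathway, protein-protein
    interaction, domain-profile similarity, shared transcription factor,
    shared microRNA targeting with hub membership) nominate candidate genes.
    Candidates are intersected with a pooled, HUGO-harmonized drug-target
    dataset built from three drug-database exports; targets and drugs are
    classified as known or novel for the phenotype, and predictions are
    validated with a search-space ROC benchmark and a literature-citation ROC
    benchmark. A seeded synthetic-data generator with a planted-truth manifest
    supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
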