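Package: eqtlBreadth
Title: Tissue Specificity of cis-eQTLs Affecting Dosage-Sensitive Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how proxies for gene dosage sensitivity (ohnologs,
    copy-number-conserved genes, haploinsufficient genes, CNV-free genes)
    relate to the incidence, tissue breadth, cross-tissue overlap and effect
    sizes of cis-eQTLs across a multi-tissue panel. Builds Bonferroni-corrected
    and posterior-probability eQTL call sets from summary association tables,
    classifies genes on five dosage-sensitivity axes, computes per-gene
    expression and eQTL tissue breadth, tissue-pair Jaccard overlap of
    eQTL-affected gene sets, coefficient-of-variation expression stability,
    enrichment contingency tests and a logistic model of eQTL status. Includes
    a synthetic-data generator that plants class-dependent eQTL incidence,
    breadth and effect-size structure so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
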