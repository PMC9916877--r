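Package: circheterosis
Title: Circular RNA Expression Heterosis Analysis for Hybrid Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing circular RNA (circRNA) expression in an
    F1-hybrid heterosis design with two parents and offspring of differing
    growth potential. Merges back-splice junction calls from two circRNA
    callers into a unified catalog, classifies genomic origin against a gene
    annotation, quantifies expression as back-spliced reads per million
    mapped reads (RPM), tests differential expression between pooled
    libraries with an exact binomial test, classifies each circRNA per F1
    genotype as additively or non-additively expressed relative to the
    mid-parent value (with above-high-parent / high-parent / low-parent /
    below-low-parent subtypes), derives the single-parent-expression
    taxonomy, predicts miRNA target sites by plant complementarity scoring
    and protein-coding potential by circular open reading frame detection,
    correlates circRNA expression with parent-gene expression, and extracts
    weighted co-expression modules with module-trait correlations and hub
    features. A fully labelled synthetic-data generator plants every
    structure the pipeline must recover, so the whole analysis is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
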