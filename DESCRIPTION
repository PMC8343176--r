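Package: rilqtl
Title: Genotyping and QTL Mapping for Low-Coverage Sequenced Recombinant
    Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline from sparse, error-prone per-line variant calls of a
    biparental recombinant inbred line (RIL) population to an ultra-high
    density genetic map and quantitative trait locus (QTL) detection.
    Includes parental diagnostic-SNP filtering, hidden Markov model genotype
    inference along chromosomes, 100-Kb window marker binning with quality
    control and segregation-distortion flagging, minimum-spanning-tree
    marker ordering with Kosambi distances and crossover-count map-length
    correction, variance-component heritability statistics, Haley-Knott and
    composite interval mapping with permutation thresholds, heterogeneous
    inbred family (HIF) allele contrasts, and candidate-gene shortlisting
    from variant-effect annotations. A synthetic-data module simulates RIL
    genomes by iterated meiosis and selfing, low-depth variant calls, and
    QTL-driven phenotypes so the whole pipeline can be exercised and
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    igraph,
    vcfR,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
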