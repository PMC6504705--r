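Package: evopattern
Title: Fixation-Pattern Analysis for Two-Condition Serial-Sampling
    Evolution Experiments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of microevolution experiments in which a haploid
    clonal population is split across two growth conditions and sampled
    serially. Variant calls from a multi-sample VCF are hard-filtered,
    encoded as binary condition-partitioned trajectories and classified as
    background, condition-fixed or random; genes are screened for variant
    hotspots by Z-score; Gene Ontology terms and intergenic k-mers are
    tested for variant enrichment (Fisher's exact test with
    Benjamini-Hochberg correction) with IUPAC motif annotation; overlap
    with differential-expression flags is tested; doubling times, growth
    rates and temporal trends (Wilcoxon rank-sum, Jonckheere-Terpstra) are
    computed from plating series. A seeded simulator generates genomes,
    annotations, variant tables with planted trajectory classes and growth
    series with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Genetics, VariantAnnotation, Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'enrichment.R'
    'evopattern-package.R'
    'growth.R'
    'hotspot.R'
    'io.R'
    'methods-VariantCallSet.R'
    'patterns.R'
    'simulate.R'
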