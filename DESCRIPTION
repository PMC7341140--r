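Package: ddGBStools
Title: Design and Quality Control for Double-Digest Genotyping-by-Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational support for double-digest genotyping-by-sequencing
    (ddGBS) studies in outbred populations: in silico single and double
    restriction digestion of reference genomes with fragment-end
    classification, size-selection capture accounting and sequencing coverage
    budgeting for enzyme selection; in-line barcode demultiplexing of raw
    reads with cut-site validation and quality trimming; and post-genotyping
    quality control including a trio Mendelian-error model, sex inference
    from X-chromosome read fractions, Ts/Tv summaries, callset concordance
    and site filtering (known sites, minor allele frequency, call rate,
    Hardy-Weinberg exact test). Deterministic simulators for genomes with
    planted cut sites, barcoded reads, trio genotypes and per-chromosome
    read counts make every stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
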