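Package: lncnat
Title: Discovery, Classification and Antisense Co-Expression Screening of
    Long Non-Coding RNAs from Stranded RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for identifying long non-coding RNAs
    (lncRNAs) from stranded RNA-seq transcript assemblies and for screening
    natural antisense transcripts (lncNATs) whose expression tracks their
    sense partners across genotype and tissue contrasts.  Covers class-code
    assignment of novel transcripts against a reference annotation, open
    reading frame based coding/structural/noncoding classification with
    positional subclasses (lncNAT, lincRNA, intronic, proximal),
    strand-specific fragment counting over exons, median-of-ratios
    normalization, a negative-binomial Wald differential-expression test
    with Bonferroni control, joint Pearson/Spearman sense-antisense
    co-expression selection, sample PCA, delta-delta-Ct relative
    quantification, and a seeded synthetic-data generator that emulates a
    two-genotype by two-tissue by three-replicate design with planted
    sense/antisense pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
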