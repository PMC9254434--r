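Package: adjukit
Title: Variant Adjudication, Graph Genotyping and Truth-Based Evaluation
    for Haploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combines candidate variant callsets (from multiple callers or
    from every sample of a cohort) into a single deduplicated, clustered set
    of non-overlapping multi-allelic sites; genotypes each site by exact
    full-length read matching to a bubble genome graph under a negative
    binomial coverage likelihood with a genotype-confidence score; filters
    calls with depth, fraction-of-read-support and simulation-based
    confidence-percentile criteria; joint-genotypes cohorts at a shared site
    list and computes a genotype distance matrix; and evaluates callsets
    against a haploid truth assembly by probe mapping with partial-credit
    edit-distance scores.  A seeded synthetic-data generator (genomes,
    implanted variants, reads, pseudo-caller VCFs) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
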