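Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and Selection Signatures
    from Diploid SNP Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and analysis of runs of homozygosity (ROH) in
    diploid SNP genotype data. Provides genotype quality control
    (missingness, minor allele frequency, exact Hardy-Weinberg test),
    a sliding-window ROH caller with PLINK-style parameters, ROH
    length-class summaries, genomic inbreeding coefficients (FROH),
    ROH-island detection from per-SNP incidence, consensus-ROH pooling
    for selection-signature screening, and a synthetic genotype
    simulator with planted autozygous tracts for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
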