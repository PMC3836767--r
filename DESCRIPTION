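Package: raremut
Title: Rare Mutant Allele Detection in Amplicon Deep Sequencing via
    Position-Specific Error Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies rare tumor-derived mutant alleles
    (EGFR exon 19 deletions, L858R, L861Q, T790M, and whole-region
    scanning) in amplicon deep-sequencing data, as used for liquid-biopsy
    analysis of plasma cell-free DNA. Per-position, per-substitution read
    error rates are modeled from a panel of normal samples; each
    substitution type is assigned a Poisson (with a conservative
    intensity floor), Poisson, or negative binomial null distribution by
    method-of-moments fitting, and mutations are called when event counts
    per 100,000 reads reach an exact upper-tail threshold. Includes
    deletion-template matching for exon 19, a simulator reproducing the
    statistical structure of amplicon error data (dominant substitution
    patterns, gamma-distributed intensity fluctuation, template-molecule
    bottleneck), and FASTQ/SAM/VCF/TSV input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    optparse,
    rlang,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation,
    rtracklayer
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
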