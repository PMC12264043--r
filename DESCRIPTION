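Package: asm6a
Title: Allele-Specific m6A Inference from Reciprocal-Cross m6A-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Statistical identification of allele-specific N6-methyladenosine
    (ASm6A) from allele-resolved m6A-seq read counts in reciprocal-cross F1
    hybrid mice. Implements allele-specific methylation levels from paired
    input/IP counts, coverage filters, strain- and parent-oriented
    allelic-imbalance metrics (log2 cpFC / mpFC), an exact binomial test with
    an input-derived null and Benjamini-Hochberg FDR control, positive-control
    cutoff calibration, classification of sites into sequence-dependent and
    parent-of-origin-dependent classes with a reproducibility filter,
    cis-regulatory SNP analyses around methylation sites (weighted SNP
    distribution score, per-position enrichment, motif-pair matrices, PWM
    variant-effect scores), allelic methylation-versus-expression linkage, and
    a seeded synthetic reciprocal-cross data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epitranscriptomics, RNASeq, StatisticalMethod, Coverage
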