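Package: allelicCall
Title: Identifying Cancer Cells from Allelic Imbalance in Single-Cell
    Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genotypes single-cell transcriptomes as cancer or normal from
    the allelic imbalance created by somatic copy-number changes. Given
    copy-number segments derived from tumour DNA and heterozygous SNPs,
    the package phases SNPs within copy-number-altered regions using
    tumour B-allele frequencies, orients per-cell allele counts to the
    major/minor haplotype, calibrates site-class error rates, per-gene
    allele-specific expression and a beta-binomial overdispersion from
    normal cells, and computes a flat-prior posterior probability that
    each cell carries the cancer genotype. Also provides subclone
    assignment, copy-number segment post-processing, genome-window
    evaluation utilities (adaptive allelic-ratio bins, ROC/AUC against
    a truth profile), a minimum-detectable-LoH calculator, and a
    seeded synthetic-data simulator for the full input bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    pROC
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
biocViews: SingleCell, Transcriptomics, CopyNumberVariation, Bayesian,
    Genetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
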