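Package: lymscape
Title: Genomic Landscape Analysis of CNS Lymphoma Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical stages for whole-genome and transcriptome studies of
    central nervous system lymphoma: detection of localized somatic
    hypermutation hotspots (kataegis), supervised mutational-signature
    decomposition by non-negative least squares with signature-specific
    cutoffs, post-processing of allele-specific copy-number segments,
    rescue of somatic variants misclassified as germline due to
    tumor-in-normal contamination, telomere-content estimation with
    tumor-cell-content correction, integration of variant types into
    gene-by-sample alteration matrices with recurrence and
    mutual-exclusivity statistics, and expression quantification with a
    contamination-dilution emulator. A seeded synthetic-cohort generator
    provides complete test data so every stage is exercisable without
    controlled-access sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
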