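Package: rbscape
Title: Somatic Genomic Landscape Analysis for Retinoblastoma Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise the somatic genomic landscape of
    retinoblastoma from tumor/normal whole-exome sequencing derivatives:
    somatic SNV/INDEL identification against a pooled germline variant
    database with pathogenicity filtering, off-target binned read-depth
    copy-number profiling with recursive binary segmentation,
    mirrored-B-allele-frequency allelic-imbalance and loss-of-heterozygosity
    calling, tumor purity and subclonal-fraction estimation from variant
    allele frequencies and loss amplitudes, chromothripsis and high-level
    amplification detection, binary event-matrix mutual-exclusivity and
    phenotype-association statistics, and k-mer based viral read screening.
    A fully parameterised synthetic tumor/normal cohort simulator with
    recorded ground truth makes every stage testable end to end without
    access-controlled patient data.
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
    Biostrings,
    data.table,
    jsonlite,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
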