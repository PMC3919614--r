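Package: imprintASE
Title: Allele-Specific Expression Analysis of Genomic Imprinting from
    Reciprocal Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects parent-of-origin allele-specific expression from
    strand-specific RNA-seq allele counts of two reciprocal mouse crosses.
    Candidate SNPs are discovered by alternative-allele-fraction and coverage
    cutoffs, strain-homozygous variants shared by both crosses are excluded,
    each site is tested for reciprocal allelic asymmetry with Fisher's exact
    test under Benjamini-Hochberg FDR control, and surviving sites are
    assigned a maternal or paternal origin, aggregated to transcript-level
    imprinting calls, and screened for parental-allele-specific transcript
    extensions downstream of known imprinted genes. Includes artifact vetting
    for pseudogene read-misassignment and minority-TRUE predictions, and a
    synthetic reciprocal-cross allele-count generator with ground truth for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
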