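Package: mztcomp
Title: Maternal and Zygotic Transcript Classification and Early Zygotic
    Dosage Compensation from Allele-Resolved Embryo RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the maternal-to-zygotic transition from
    single-embryo RNA-seq of a two-strain cross. Calls SNPs fixed between the
    parental strains from base-count pileups, partitions per-gene RPKM into
    maternal- and paternal-allele components in proportion to
    allele-informative read counts, classifies genes as maternal, zygotic or
    maternal+zygotic by k-medians clustering of allele-resolved female time
    profiles with correlation-based propagation to SNP-free genes, and scores
    early zygotic dosage compensation of X-linked genes as the through-origin
    least-squares slope of female on male expression. A synthetic-data
    generator emulates the 24-embryo staged design with known ground truth so
    every stage of the pipeline is verifiable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
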