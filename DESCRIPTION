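Package: parthenomir
Title: Small RNA-Seq Tag Annotation, Novel miRNA Discovery and
    X-Inactivation Inference
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale small RNA sequencing analysis pipeline for
    primate embryonic stem cell lines: adaptor trimming and read
    cleaning, collapsing reads into unique sequence tags, exact genomic
    mapping, priority-ruled annotation against rRNA/miRNA/repeat/exon/
    intron tracks, novel miRNA hairpin prediction by weighted base-pair
    folding with Dicer-site and stem criteria, TPM normalisation with a
    Poisson random-bin noise filter, 10-kb genomic miRNA cluster
    grouping, two-library differential expression, and an
    X-chromosome-inactivation caller that compares chromosome-wide
    miRNA dosage against a male baseline with chromosome 1 as control.
    Includes a synthetic-data generator that plants miRNA hairpins,
    clusters and X-dosage regimes with full ground truth, so every
    stage is verifiable without large sequencing downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
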