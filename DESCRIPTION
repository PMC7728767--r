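Package: nfypipe
Title: Knockdown Transcriptome Analysis for the NF-Y CCAAT-Box Regulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing transcriptome changes after knockdown of the
    CCAAT-box binding transcription factor NF-Y in neuronal and non-neuronal
    cells. Implements two-group differential expression calling with
    low-expression and non-neuronal gene filters, a promoter-proximal motif
    centrality test (centered-window binomial test on per-sequence best PWM
    sites), functional-annotation population profiling with Ward hierarchical
    clustering and cross-cell-type correlation, consensus ChIP peak building
    and peak-to-TSS target assignment, and estimation of NF-YA exon-3
    inclusion (percent spliced in) from splice-junction read counts. A
    synthetic-data module generates every input with known ground truth so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
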