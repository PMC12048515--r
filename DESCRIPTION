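Package: NmSplice
Title: SnoRNA-Guided 2'-O-Methylation and Splicing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for studies linking small nucleolar RNA
    (snoRNA) expression to spliceosomal RNA 2'-O-methylation and downstream
    splicing changes. Implements pattern-based differential probe selection
    with hypergeometric snoRNA enrichment for multi-site tumour microarrays,
    RNase-H protection (Nm-VAQ) percent-methylation quantification by the
    delta-delta-Ct method, RibOxi-seq read 3'-end pileup and neighbour
    normalised Nm scoring with differential site detection, percent-spliced-in
    (PSI) statistics with the delta-PSI/FDR/read-count significance filter,
    intron retention and splicing efficiency summaries, and patient-pair
    association of exon inclusion with snoRNA expression including lowest-p
    threshold dichotomisation. Seeded simulators generate every input with
    planted ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
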