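Package: methtile
Title: Tiled CpG Probe Analysis of Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed 50-CpG probe tiling and quantification of CpG
    methylation from bisulfite-sequencing coverage files, differential
    methylation calling by binomial logistic regression with
    likelihood-ratio p-values and Benjamini-Hochberg correction,
    histone-mark based enhancer classification with lineage-exclusive
    probe assignment, transcription-factor binding-site methylation
    scoring, hypergeometric motif enrichment with a PWM scanner, and
    preranked gene-set enrichment scores. Includes a synthetic
    methylome generator with a known truth table so that every stage of
    the pipeline can be validated end to end without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
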