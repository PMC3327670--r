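Package: dualseq
Title: Dual Quantitative and Qualitative RNA-Seq Analysis of Cardiac Hypertrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end RNA-Seq pipeline that analyses transcriptomes both
    quantitatively and qualitatively, as applied to pathological (pressure
    overload) versus physiological (exercise) cardiac hypertrophy. From
    filtered read alignments and an exon annotation it computes exon- and
    gene-level count matrices and RPKM (reads per kilobase of exon model per
    million mapped reads) expression values; calls differentially expressed
    genes with an equal-variance t-test, a log-1.5 fold-change threshold and
    an expression floor, and classifies turned-on and oppositely regulated
    gene sets; detects exon inclusion/exclusion events with a two-sided
    Fisher exact test on exon-versus-rest-of-gene contingency tables combined
    with a Beta-Binomial posterior sign-error rate and known alternative
    splicing labels; tests hypergeometric pathway enrichment of the resulting
    gene lists; and scans strand-aware 1 kb upstream promoter sequences for
    consensus transcription-factor motifs. A fully specified synthetic-data
    generator with spiked ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    rtracklayer,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
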