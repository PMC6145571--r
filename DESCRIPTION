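Package: ovimirnome
Title: Cross-Species miRNome Assembly and Age-Group Differential
    Expression for Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles a non-overlapping, cross-species mature microRNA
    annotation (a "miRNome") on a reference genome, quantifies small-RNA
    sequencing reads over it, and tests age-group differential expression
    with TMM normalization, precision-weighted log-cpm, and moderated
    t-statistics.  A delta-delta-Ct module performs qRT-PCR relative
    quantification with data-driven reference-miRNA selection, and a
    reporting module cross-tabulates sequencing and qPCR calls.  A
    synthetic-data generator emulates a cardiopulmonary developmental
    study design (four tissues, three age groups) with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
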