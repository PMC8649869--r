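Package: dropscreen
Title: Pooled shRNA Dropout Screen Analysis with Acute-Arm Subtraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end candidate discovery for pooled shRNA barcode dropout
    screens of drug resistance: simulation of barcoded libraries, arm-structured
    screens and RNA-seq counts with planted ground truth; barcode counting from
    FASTQ with mismatch-tolerant demultiplexing; CPM normalization and per-shRNA
    depletion scoring with acute-arm subtraction and gene-level candidate tiers;
    an in-house negative-binomial likelihood-ratio differential expression test
    with Benjamini-Hochberg adjustment; gene-set overlay and Venn summaries;
    hypergeometric over-representation and GSEA-style running-sum enrichment;
    and small closed-form assay quantifications (delta-delta-Ct, ChIP fold
    enrichment, caliper tumor volume). A seeded demo pipeline produces a
    machine-readable run report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    edgeR,
    DESeq2
Config/testthat/edition: 3
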