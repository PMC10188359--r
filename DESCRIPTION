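Package: scmultimark
Title: Multifactorial Single-Cell Chromatin Profile Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-target single-cell chromatin
    profiling (barcoded CUT&Tag-style fragment files): fragment import,
    deduplication and per-cell QC; barnyard species-mixing collision rates;
    TF-IDF/SVD (LSI) cell typing with k-means and normalized mutual
    information; a per-cell, per-gene, per-target Poisson fragment-enrichment
    test with Benjamini-Hochberg correction; cross-mark co-occurrence
    statistics (Cramer's V, bivalency scores, per-cell target proportions);
    and trajectory/group comparisons. Includes a synthetic fragment-data
    generator with planted ground truth so the full pipeline is testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    methods,
    utils,
    uwot
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    jsonlite
Config/testthat/edition: 3
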