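Package: orphanRNA
Title: Discovery and Clinical Analysis of Orphan Non-Coding RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and characterising orphan non-coding RNAs
    (oncRNAs): small-RNA species that are detected in tumors but essentially
    absent from normal tissue and non-cancerous biofluids. Implements
    DUST-based low-complexity read filtering, cross-sample locus merging with
    coverage-peak splitting of long loci, presence/absence matrix
    construction, a cascading cancer-emergence caller (biofluid-atlas,
    normal-tissue, prevalence, Fisher-exact enrichment with
    Benjamini-Hochberg FDR, annotation and serum filters), digital-barcode
    statistics (Jaccard similarity, nearest-centroid tissue-of-origin
    classification, subtype association, chromatin-accessibility
    association), and circulating oncRNA burden analysis with Kaplan-Meier
    stratification and log-rank testing. A seeded synthetic-cohort simulator
    with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    survival,
    data.table,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
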