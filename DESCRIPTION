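Package: sigconnect
Title: Connectivity Mapping and Enrichment Pipeline for High-Throughput
    Transcriptomics QC and Reproducibility Assessment
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the reproducibility of targeted and
    whole-transcriptome count assays in chemical screening: replicate-level
    quality control, log2 fold-change profiling, differential expression
    with batch handling, query-signature construction, connectivity mapping
    against a reference profile database with five scoring algorithms
    (signed Jaccard, gene set total enrichment, extreme cosine, Pearson
    and Spearman), top-k retrieval benchmarking, weighted Kolmogorov-Smirnov
    gene set enrichment with permutation normalization, and hierarchical
    clustering of enrichment scores. A synthetic-data module simulates
    negative-binomial counts with mechanism programs, batch effects,
    surrogate panels and a decoy-laden reference database so the whole
    pipeline can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, ape
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr
Config/testthat/edition: 3
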