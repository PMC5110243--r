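Package: cortexcomp
Title: Comparative Analysis of Cortical Progenitor Transcriptomes and Mitotic Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative single-cell analysis of human and chimpanzee
    cerebral-organoid cortical progenitors: signature scoring and
    reference-correlation cell classification for log2(FPKM+1) expression
    matrices, thresholded intercellular correlation networks with minimum
    spanning tree pseudotime, cross-species consensus-sequence masking,
    rank-sum z-score differential expression with standard-deviation
    specificity thresholds, mitotic phase duration and spindle orientation
    statistics, and cell-cycle parameter estimation from cumulative EdU
    labeling curves. Includes a seeded synthetic-data generator with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
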