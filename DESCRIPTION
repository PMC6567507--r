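Package: hairpin2pare
Title: Interlaced Small-RNA and Degradome (PARE) Analysis of Plant miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for de-novo plant miRNA and
    isomiR ascertainment from small RNA sequencing: adapter trimming, tag
    collapsing and RPM filtering, hairpin-precursor folding with a
    dynamic-programming secondary-structure model, miRNA-star prediction
    from duplex geometry, family assignment and naming, TMM-normalized
    negative-binomial GLM differential expression across a two-treatment,
    three-timepoint heat-stress design, and degradome (PARE) validation of
    miRNA-guided cleavage sites with permutation p-values and t-plot
    tables. Includes a synthetic-data generator that plants precursors,
    isomiRs, fold changes and cleavage peaks with a full ground-truth
    table, so every stage can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
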