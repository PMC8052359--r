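Package: abeditr
Title: RNA Off-Target Profiling and Amplicon Quantification for Adenine Base Editors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects guide-RNA-independent adenosine-to-inosine (A-to-I) RNA
    editing induced by adenine base editors (ABEs) from treated/control
    RNA-seq pileup tables, subtracts endogenous editing, performs call-set
    algebra across variant callers, extracts efficiency-stratified sequence
    contexts and information-content motif logos around edited adenines, and
    quantifies on-target DNA editing from amplicon deep-sequencing reads
    (per-protospacer-position A-to-G conversion, A-to-nonG byproducts, indel
    frequency, editing-window summaries, and log2 fold-change tables). A
    synthetic-data generator plants ground-truth edits in toy transcriptomes
    and amplicon read sets so every stage of the pipeline is verifiable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    Biostrings,
    vcfR,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
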