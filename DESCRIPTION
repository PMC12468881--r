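Package: lncatlas
Title: Multi-Tissue lncRNA Atlas Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the analysis layer of a
    multi-tissue long non-coding RNA (lncRNA) expression atlas: expression
    filtering and normalization (CPM and median-of-ratios), genomic-context
    classification of lncRNAs relative to protein-coding genes,
    housekeeping and tissue-specific classification from cross-tissue
    expression summaries, cross-species positional-conservation calling on
    lifted coordinates, cis-target assignment, co-expression module
    eigengene/membership statistics and hub selection, differential
    expression thresholding, competing endogenous RNA (ceRNA) network
    assembly, and stage-wise temporal profile matching. A synthetic-data
    generator with planted ground truth makes the whole pipeline testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
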