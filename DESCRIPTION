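Package: platevdj
Title: Clone-Level VDJ Amplicon Consolidation for Multiplexed Plate Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing and consolidation of clonal B-cell and T-cell receptor
    variable-domain amplicons from multiplexed, well-barcoded plate libraries.
    Implements paired-end read merging, well demultiplexing, chain assignment by
    constant-region primer, template-switch oligo removal, quality and length
    filtering, amplicon sequence variant (ASV) denoising, IMGT-style
    framework/CDR segmentation with region-based quality filters and amino-acid
    binning, a replicate-aware star-rating confidence score with aberrant
    light-chain removal, sample complexity summaries, high-confidence
    heavy/light pair selection, a gradient-boosted pairing classifier harness,
    SQLite export, and a synthetic plate simulator providing ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    DBI,
    RSQLite,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
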