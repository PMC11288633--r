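Package: tRNAcharge
Title: Charge tRNA-Seq Read Processing, Reference Masking, and Aminoacylation Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes barcoded, UMI-tagged charge tRNA-Seq reads into
    per-tRNA aminoacylation charge, relative expression, and modification
    signatures. Implements demultiplexing by 3' adapter barcode, 5' UMI
    extraction, guaranteed-optimal Smith-Waterman local alignment with
    mask-aware scoring, iterative reference masking driven by
    misincorporation frequencies with a grid search over the masking
    parameters, UMI occupancy quality control, charge titration model
    fitting with a per-transcript abundance correction factor, and
    first-order aminoacylation decay fitting with bootstrap confidence
    intervals. A synthetic-data generator produces references, reads,
    titration series, and decay series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
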