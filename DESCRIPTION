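Package: mpraic
Title: Motif Information Content Analysis of MPRA Enhancers and Silencers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of massively parallel reporter assay (MPRA) libraries of
    candidate cis-regulatory sequences: activity calling from barcoded
    DNA/cDNA counts (enhancer, silencer, inactive classes against a basal
    promoter, with autonomous-activity calls for promoterless assays),
    biophysically predicted transcription factor occupancy from
    position-weight-matrix energy models, Boltzmann-entropy motif information
    content summarizing motif number and diversity, motif co-occurrence and
    positional-bias diagnostics, and cross-validated classifiers (occupancy
    logistic regression, information-content models, and a canonical 6-mer
    spectrum SVM) with a random-motif null. Includes a synthetic MPRA
    generator that plants motifs into sequence libraries and simulates
    overdispersed barcode counts so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
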