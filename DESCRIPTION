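Package: tflogic
Title: Inference of Transcription Factor Regulatory Logic and Collaborations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers how transcription factors (TFs) control their target
    genes by combining a TF-DNA binding network with ternarized time-series
    gene expression. A two-stage procedure first assigns each TF in a
    regulatory module an individual role (activator/repressor crossed with
    necessary/sufficient) through an EM-style Bayesian labeling with
    permutation-based significance, and then mines minimal significant
    multi-TF collaborative interactions with a bottom-up association-rule
    search scored by an affinity function over ternary expression states.
    Includes a synthetic regulatory-network simulator with planted
    interactions and binding-only decoy edges, and evaluation utilities
    (precision/recall/specificity, rank-based AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
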