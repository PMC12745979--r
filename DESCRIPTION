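Package: clmprobe
Title: Controlled Probing of Sequence-Conditioned Chemical Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale harness for auditing what sequence-to-compound
    transformer models actually learn. Generates synthetic protein
    family / analog-series universes with known ground truth, curates
    ChEMBL-style activity records into deduplicated sequence-compound
    pair datasets, partitions them by sequence or by protein family,
    dilutes multi-target compounds, trains a scaled-down encoder-decoder
    transformer, and measures sampling-based compound and core
    reproduction, memorization fractions, nearest-neighbor Tanimoto
    similarity, cumulative sequence randomization curves, and motif
    masking with Mann-Whitney statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
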