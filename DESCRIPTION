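Package: pkaGraph
Title: Microstate pKa Prediction with Paired Graph Isomorphism Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts microstate pKa values of small molecules with a
    twin-tower graph isomorphism network (GIN) that reads the conjugate
    acid-base pair of a protonation transition as two molecular graphs.
    Provides protonation-state enumeration at a reference pH, transfer
    learning (pre-training on large calculated-pKa corpora followed by
    fine-tuning on experimental values with batch-mixing regularisation),
    sequential prediction of full protonation ladders with ensemble
    uncertainty estimates, and the accompanying evaluation protocol
    (MAE/RMSE with median and percentile intervals over repeated
    training runs, and overlap filtering between data sets).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    igraph,
    withr,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
RoxygenNote: 7.3.3
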