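Package: edsmiles
Title: Structure Recognition Analysis for SMILES Encoder-Decoder Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains checkpointed GRU encoder-decoder models that translate
    randomized SMILES into canonical SMILES and quantifies, across training
    progress, how much chemical structure the models have learned: exact and
    per-character translation fidelity, substructure agreement between input
    and decoded molecules (MACCS and ECFP Tanimoto), systematic biases of
    mispredicted structures (string length and molecular weight inflation),
    and the quality of the latent bottleneck as a molecular descriptor
    (gradient-boosted downstream classification and UMAP chemical-space
    maps). Ships a synthetic molecule generator so the whole analysis runs
    at desk scale without external compound libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ChemmineOB,
    jsonlite,
    xgboost,
    pROC,
    uwot,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
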