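Package: atcct
Title: Drug-ATC Code Association Prediction with a Convolution-Transformer Encoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between drugs and Anatomical Therapeutic
    Chemical (ATC) classification codes at hierarchy levels 1-4, cast as
    binary link prediction. Three drug-drug similarity channels (Tanimoto on
    1024-bit circular fingerprints, Jaccard on drug-drug-interaction partner
    sets, Jaccard on side-effect profiles) are combined with a
    weighted-hierarchical ATC-code similarity and leakage-masked drug-ATC
    association features into per-pair feature matrices, which a
    convolution-transformer encoder scores with a sigmoid head. Includes
    balanced negative sampling, stratified cross-validation, AUROC/AUPRC
    evaluation, label-perturbation robustness studies, and a seeded synthetic
    corpus generator with planted hierarchical signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
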