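Package: tmfuf
Title: Triple Matrix Factorization for Comprehensive Drug-Drug Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts conventional (binary) and comprehensive (enhancive or
    degressive, i.e. signed) drug-drug interactions for new drugs from binary
    side-effect feature profiles. The model couples a signed interaction
    network to drug features through a triple matrix factorization: the
    adjacency matrix is factorized into a low-rank latent interaction space,
    latent coordinates are regressed on observed features by SIMPLS partial
    least squares, and the resulting symmetric feature projection matrix
    scores arbitrary drug pairs bilinearly. Includes cold-start
    cross-validation schemes for the new-drug-versus-known and
    new-drug-versus-new screening tasks, ROC/PR evaluation with a sign-flip
    protocol for signed interactions, latent-factor tuning, significant
    side-effect pair extraction, and a synthetic benchmark generator with
    planted bilinear structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
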