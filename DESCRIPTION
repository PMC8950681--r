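Package: idpred
Title: Per-Residue Prediction of Intrinsically Disordered Protein Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts intrinsically disordered regions (IDRs) of proteins at
    per-residue resolution from sequence-derived features. Implements three
    topology- and composition-based feature tracks -- persistent entropy of a
    Vietoris-Rips filtration built on a cylindrical sequence embedding, and
    min-max scaled dipeptide/tripeptide corpus probabilities (PCAA2/PCAA3) --
    alongside 32 classical channels (PSSM profile columns, physicochemical
    scales, disorder propensities, Shannon and topological entropy), assembled
    into a 35 x L per-residue feature matrix. A deep classifier (MLP into a
    VGG19-style convolutional backbone with a skip connection into a second
    MLP) is trained by mini-batch stochastic gradient descent on binary
    cross-entropy and evaluated with sensitivity, specificity, balanced
    accuracy and the Matthews correlation coefficient. A synthetic-corpus
    generator with planted compositional disorder signal makes every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
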