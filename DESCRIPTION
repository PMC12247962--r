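Package: cytogp
Title: Gaussian Process Attention Networks for Longitudinal Single-Cell
    Cytometry Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts subject-level clinical outcomes from longitudinal
    single-cell cytometry (flow or mass cytometry) and single-cell
    RNA-seq data while keeping single-cell resolution.  A cell-level
    autoencoder embeds marker expression into a low-dimensional latent
    space, a sparse variational Gaussian process with inducing points
    maps each cell embedding to a scalar, per-timepoint gated attention
    pools the ragged cell sets into a subject representation, and a
    logistic (or softmax) head produces the outcome probability.  The
    whole stack is trained end-to-end by maximising a Monte-Carlo
    evidence lower bound.  A Gumbel-Softmax mask explainer scores global
    marker importance on the trained model.  Includes arcsinh and
    scRNA-seq preprocessing, subject-stratified cross-validation,
    robustness protocols (cell subsampling, missing-visit masking), a
    batch-effect diagnostic based on layer activation scores and the
    Kruskal-Wallis test, and a synthetic cohort simulator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
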