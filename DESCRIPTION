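Package: tnmpls
Title: Regularized Partial Least Squares for Triple-Network Functional
    Connectivity and Phenotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links resting-state functional connectivity of the salience,
    frontoparietal and default-mode networks (the triple network model) to
    behavioural and clinical phenotypes through sparse two-domain partial
    least squares. Provides phenotype derivation (family-history density
    scoring, log transforms of drinking measures, alcohol-preference
    contrasts, Kaiser-rule principal-component compression), connectome
    construction (Pearson functional connectivity, edge vectorization under
    the triple-network coupling mask), a deterministic soft-thresholded
    sparse PLS solver with per-domain L1-ball regularization and deflation,
    block-permutation inference on network-pair contributions, signed
    regional strength substrates, leave-one-out stability analysis, and a
    synthetic cohort generator with planted cross-domain latent structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
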