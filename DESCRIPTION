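Package: mirblood
Title: Blood Metabolite Modelling and Milk FT-MIR Prediction for Transition Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-part analysis of blood metabolic profiles in
    early-lactation dairy cows: (i) phenotypic-variance modelling of plasma
    traits (3-SD editing, log10 transformation, Spearman correlations, a
    linear mixed model with a random herd effect fitted by REML,
    Bonferroni-adjusted least-squares means, and logistic odds ratios for
    binarized total bilirubin) and (ii) prediction and risk classification of
    blood traits from milk Fourier-transform mid-infrared (FT-MIR) spectra
    (water-region masking, standard normal variate scatter correction, PCA
    spectral outlier flagging, NIPALS partial least squares regression with
    leave-one-out cross-validation, stratified external validation, and
    PLS-DA against published ketosis and negative-energy-balance risk
    thresholds). A herd-structured synthetic-data generator with a Gaussian
    copula over the trait correlations and Beer-Lambert-style spectra makes
    every pipeline stage testable without access to raw herd data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
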