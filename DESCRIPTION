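Package: steatoPK
Title: Pharmacokinetic and Statistical Analysis of Diet-Induced Hepatic Steatosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for drug-cocktail pharmacokinetics in a mouse
    model of periportal steatosis. Fits the single-peak elimination curve
    x(t) = t * exp(B - A*t) to concentration time courses by per-replicate
    least squares, extracts peak time, peak concentration, half-life and
    decay-phase AUC, and quantifies pooled parameter uncertainty per dietary
    condition with an adaptive parallel-tempering MCMC sampler (Geweke
    burn-in, effective sample size, posterior-predictive credibility bands).
    Includes group statistics (one-way ANOVA, Tukey HSD, Pearson correlation
    matrices with Benjamini-Hochberg adjustment), tile-based steatosis
    surface aggregation and severity grading, and a calibrated synthetic
    data generator emulating the study's measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    numDeriv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
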