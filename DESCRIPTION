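Package: quantalmix
Title: Quantal Dose-Response Analysis and Synergism Assessment for
    Larvicidal Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing quantal (dead/alive) concentration-mortality
    bioassays of microbial larvicides. Fits binomial logit regressions of
    mortality on natural-log concentration, estimates lethal concentrations
    (LC50 and other quantiles) with Fieller fiducial limits and heterogeneity
    correction, tests parallelism of regression lines by quasi-likelihood
    F-tests, computes expected mixture LC50s under the simple-similar-action
    null model, and derives synergism factors and relative potencies for
    two-toxin mixtures. Includes the published Aedes aegypti bioassay tables
    for Bacillus thuringiensis israelensis Cry and Cyt delta-endotoxins as
    built-in fixtures, and a seeded simulator of replicate-well bioassays
    (binomial or beta-binomial) for parameter- and synergy-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
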