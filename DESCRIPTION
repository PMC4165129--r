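Package: ripetime
Title: Interval-Censored Bivariate Modelling of Climacteric Fruit Ripening Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates, per tomato genotype, the number of days from anthesis
    to the first sign of ripening and the length of the climacteric ripening
    phase from repeated ordinal colour-stage observations. Fruit-level event
    times are interval censored by the observation schedule; the two event
    times are modelled jointly as a bivariate Gaussian linear model with a
    plant-level bivariate random effect, and the marginal likelihood is
    evaluated by Gauss-Hermite quadrature over exact bivariate-normal
    rectangle probabilities. Includes maximum-likelihood fitting,
    likelihood-ratio covariate selection and genotype contrasts, a seeded
    synthetic-data generator reproducing the generative model, and the
    companion quantification chains for qPCR relative expression
    (window-of-linearity efficiencies, normalized relative quantities,
    geNORM reference-gene stability, mean-centred dataset merging, ANOVA
    with protected LSD) and cuvette-based ethylene emission rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
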