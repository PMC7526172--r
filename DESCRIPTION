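Package: fecage
Title: Age-Specific Fecundity Effects of Deleterious Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian analysis of age-specific fecundity effects of deleterious
    mutations in a paired mutant/wildtype vial design. Provides a validated data
    model for vial-level egg counts, a synthetic-data generator emulating the
    experimental design with known ground truth, hierarchical Poisson and
    binomial GLMMs fit by MCMC (JAGS) with the study's prior and chain settings,
    posterior-derived estimands (deleteriousness, reproductive-aging rate,
    interval-specific aging, aging acceleration, among-line variance) with
    central credibility intervals and two-tailed posterior probabilities
    (p_mcmc), and a Kendall rank-correlation suite for age pleiotropy.
License: MIT
Encoding: UTF-8
Imports:
    rjags,
    jsonlite,
    stats,
    utils
Suggests:
    coda,
    lme4,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
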