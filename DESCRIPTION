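Package: gammaprev
Title: Gamma Allele-Frequency Distributions and Prevalence Prediction Across Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Macroecological analysis of across-host allele-frequency data from
    shotgun metagenomes. Implements the stationary gamma distribution of the
    Stochastic Logistic Model (SLM) of strain dynamics, its coverage-aware
    sampling distribution of read counts, and zero-free-parameter predictions
    of allelic prevalence under a minor-allele detection cutoff. Provides
    distribution data-collapse and gamma-versus-lognormal fit diagnostics,
    Taylor's Law mean-variance regression with bootstrap confidence intervals,
    gamma parameterizations of mutation-selection balance as evolutionary
    alternatives, Langevin (Euler-Maruyama) simulators used as numerical
    oracles, permutation tests relating prediction error to observed
    prevalence and to strain structure, and a seeded synthetic-cohort
    generator that emulates the statistical structure of processed
    metagenomic allele-count data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
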