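Package: paleoherd
Title: Bayesian Sex-Specific Mortality and Product Yields from Cattle
    Kill-Off Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sex-specific cattle survival curves from unsexed
    archaeological age-at-death (kill-off) profiles by borrowing
    age-dependent sex-ratio information from census data on modern
    unimproved herds. A Poisson regression with herd random effects and a
    log-population offset is fitted to the modern data by MCMC; the
    resulting posterior over the sex ratio r(t) = exp(beta2 + beta3 t) is
    combined with a Dirichlet-multinomial model of the ancient death
    counts to yield posterior sex-partitioned survivorship, with
    imputation of ambiguous age-class assignments. Posterior survival
    curves are converted into lifetime milk, meat-and-offal, macronutrient
    and calorie yields, feed-cost proxies, herd growth rates and the
    economic efficiency of calorie production. Includes synthetic-data
    generators, a simulate-refit HPD-coverage validation protocol, random
    kill-off-strategy search with Pareto filtering, MCMC diagnostics and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
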