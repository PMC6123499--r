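Package: depsim
Title: Dynamic Microsimulation of Dependency and Care Needs in Ageing
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time dynamic microsimulation toolkit for projecting
    care-need dependency in an ageing population. Builds a weighted synthetic
    base cohort from pooled multi-study extracts (raking to population
    margins, cloning to unit weights, subsampling), estimates
    per-characteristic transition models from two-wave panel data by weighted
    logistic regression, advances individuals monthly through
    sociodemographic, behavioural, disease, sensory, cognitive and
    physical-dependency states to a projection horizon with lifetable
    mortality, allocates dementia probabilistically outside the simulation,
    and reports dependency counts and prevalence by age band, multimorbidity
    cross-tabulations, birth-cohort independence traces, and Sullivan-method
    health expectancies with uncertainty ranges over repeated seeded runs.
    Dependency is classified on the four-level interval-of-need scale
    (independent, low, medium, high) from activities-of-daily-living items,
    continence and cognition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
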