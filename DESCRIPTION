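Package: demsim
Title: Dynamic Microsimulation of Dementia Prevalence, Health Burden and Caregiving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuous-time dynamic microsimulation of dementia in an open
    national population. Actors are created from historical and projected birth
    cohorts with immigration and emigration, aged through age- and sex-specific
    dementia incidence, excess mortality (a hazard ratio on a Lee-Carter-style
    improving baseline), health-related quality of life (HUI3), informal
    caregiving and sectoral health-care costs. Counterfactual twins computed
    under common random numbers yield per-person years of life lost (YLL) and
    health-adjusted years of life lost (HYLL); a scenario engine expresses
    delayed incidence, reduced dementia mortality and life-expectancy variants;
    and a deterministic cohort-component oracle provides exact-in-expectation
    validation of the stochastic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
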