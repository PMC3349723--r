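Package: hiasim
Title: Dynamic Multi-State Population Health Modelling for Health Impact
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamic, Markov-type population health model for quantitative
    health impact assessment.  Projects how a change in a single risk factor
    propagates through disease incidence, prevalence and excess mortality
    into population-level outcomes (life expectancy, disease-free life
    expectancy, prevalent case counts) for a reference scenario versus one
    or more intervention scenarios.  Uses a partial micro-simulation:
    stochastic simulation of individual risk-factor biographies combined
    with deterministic disease life tables per biography.  Includes a
    parameter-estimation module that back-calculates baseline rates from
    population-level incidence, prevalence, relative risks and mortality,
    and estimates net transition probabilities that hold age-specific
    risk-factor prevalence constant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
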