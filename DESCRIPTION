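Package: beephys
Title: Respirometry Trace Processing and Climate-Trait Modelling for
    Discontinuous Gas Exchange in Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how insect metabolic rate and the frequency
    of discontinuous gas exchange vary and co-vary along climatic gradients.
    Converts flow-through respirometry CO2 traces into rates of CO2
    production (with baseline drift correction, STP flow correction and
    gas-exchange cycle detection), computes saturated vapour pressure and
    vapour pressure deficit for collection sites, fits a priori sets of
    linear mixed models with crossed random intercepts and compares them by
    AIC, Akaike weights and marginal R-squared (a strong-inference test of
    the metabolic cold adaptation and hygric hypotheses), and regresses
    per-species trait-covariation slopes on species' climates. A synthetic
    data module simulates respirometry traces with known ground truth and
    trait tables with a known effect structure so every stage of the
    pipeline can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
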