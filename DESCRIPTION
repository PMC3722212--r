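Package: pcisurvey
Title: Potential Conflict Index Analysis for Geographically Stratified
    Attitude Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of geographically stratified Likert-scale
    attitude surveys, motivated by studies of public acceptance of illegal
    hunting of large carnivores in Scandinavia. Provides a synthetic survey
    generator with municipality/county/country structure, the first- and
    second-generation Potential Conflict Index (PCI) with bootstrap confidence
    intervals, Cronbach's alpha, Spearman rank correlations with small-sample
    standard errors, binomial and Gaussian mixed models with random
    intercepts, likelihood-ratio backward elimination, and a reproducible
    simulate/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
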