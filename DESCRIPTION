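Package: tojpsych
Title: Temporal Order Judgment Psychophysics: QUEST Simulation, Psychometric
    Fitting, and Clinical Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing multisensory temporal order judgment (TOJ)
    experiments in clinical populations. Simulates QUEST-driven adaptive TOJ
    sessions for synthetic observer cohorts (healthy controls and patient
    groups with psychometric and psychopathological profiles), fits
    cumulative-Gaussian psychometric functions by maximum likelihood to
    estimate the point of subjective equality (PSE) and just noticeable
    difference (JND), applies interquartile-range participant exclusion,
    performs permutation-based mixed-design ANOVA with an age covariate
    (Freedman-Lane scheme) with generalized eta squared, permutation post-hoc
    t-tests with Bonferroni correction, Jeffreys-Zellner-Siow Bayes factors,
    Kendall tau-b screening of precision against clinical scales and
    medication equivalents, and negative-binomial regression of positive
    psychotic symptom scores on temporal precision with Nagelkerke pseudo
    R-squared. A pipeline driver reproduces the full analysis from trial and
    participant tables to a statistics report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
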