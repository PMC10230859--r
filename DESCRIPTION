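Package: prndsim
Title: Pipeline Simulation and Economic Evaluation of Pooled Funding for
    Neglected-Disease Clinical Trials
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete event simulation of a poverty-related and
    neglected-disease (PRND) research and development pipeline funded by a
    pooled mechanism for late-stage clinical trials, together with the
    downstream health and economic benefits model. Candidates move through
    preclinical and phase I-III trial stages with archetype-specific costs,
    durations and success probabilities; product launches trigger incidence
    and treatment-coverage ramps from which averted cases, deaths, YLLs,
    YLDs, DALYs and treatment costs are computed. A cost layer (operations,
    start-up, health system strengthening, phase III spend, vaccine
    procurement) and an economics layer (discounting, benefit-cost ratios,
    cost per DALY and death averted, ICERs) complete the evaluation. A
    synthetic-data module generates portfolios and disease-parameter tables
    so the full chain is testable without proprietary inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
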