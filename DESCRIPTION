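Package: mitracea
Title: Cost-Effectiveness Modelling of Transcatheter Mitral Valve Repair
    in Heart Failure with Secondary Mitral Regurgitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree plus Markov cohort model comparing MitraClip
    transcatheter edge-to-edge repair with optimal medical therapy in heart
    failure patients with secondary mitral regurgitation, from a Chinese
    healthcare-payer perspective. Provides configuration-driven parameter
    handling with cost derivation arithmetic (weighted means, CPI inflation,
    currency conversion) and gamma/beta moment matching, a monthly-cycle
    NYHA-state cohort engine with half-cycle correction, incremental
    cost-effectiveness and net-monetary-benefit computation, device-price
    scenario and threshold analyses, calibration of unreported parameters to
    published outcomes, one-way (tornado) and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves, and an
    individual-level microsimulation that serves as an independent oracle
    for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
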