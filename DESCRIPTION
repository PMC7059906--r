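Package: lifelost
Title: Excess Life Years Lost After Disease Onset
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of tau-restricted remaining life expectancy and Life
    Years Lost (LYL) after disease onset from individual-level cohort data,
    using landmark-conditioned product-limit survival with delayed entry
    (left truncation) and Aalen-Johansen cause-specific cumulative incidence
    to decompose life lost into competing causes of death. Per-age estimates
    can be averaged over the observed age-at-onset distribution, and
    non-parametric bootstrap confidence intervals are provided together with
    diagnostics for risk-set size and bootstrap convergence. Diseased cohorts
    can be compared against reference populations given as individual-level
    data, standard life tables (piecewise-exponential survival from
    age-specific mortality rates or survivor proportions), or fully
    aggregated tables of rates and new-case counts. Includes a simulator for
    populations with disease onset, competing causes of death and
    administrative censoring, with closed-form constant-hazard oracles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
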