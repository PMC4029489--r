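Package: mdscea
Title: Markov Cohort Cost-Effectiveness Model for Azacitidine in High-Risk
    Myelodysplastic Syndromes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lifetime Markov cohort model for the cost-effectiveness of
    azacitidine against conventional care regimens (best supportive care,
    low-dose and standard-dose chemotherapy) in high-risk myelodysplastic
    syndromes. Provides a pseudo individual-patient-data simulator for
    right-censored overall survival, time to acute myeloid leukaemia and
    treatment cessation; parametric survival fitting, AIC-based family
    selection and extrapolation; conversion of fitted curves to per-cycle
    competing-risk transition probabilities; five-week-cycle cohort
    simulation with discounted cost, life-year and QALY accumulation;
    per-cycle health-state costing from unit costs, drug regimens and
    annualised adverse-event rates; incremental cost-effectiveness analysis
    with patient-count-weighted pooled comparators and net-monetary-benefit
    threshold decisions; and parametric probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    graphics,
    jsonlite,
    MASS,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
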