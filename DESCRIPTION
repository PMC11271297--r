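Package: her2cea
Title: Cost-Utility and Budget-Impact Modelling of Neoadjuvant HER2-Targeted
    Therapy for Early Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Five-state Markov cohort model (event free, locoregional
    recurrence, metastasis, remission, death) for the cost-utility analysis of
    neoadjuvant/adjuvant HER2-targeted treatment strategies in HER2-positive
    early breast cancer, parameterised for the Sri Lankan health system.
    Provides the deterministic cohort engine with time-in-state cost clocks,
    incremental cost-effectiveness analysis with dominance assessment,
    threshold (price-reduction) analysis, one-way deterministic sensitivity
    analysis (tornado), probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, a five-fiscal-year budget impact
    analysis, and a patient-level microsimulation oracle plus synthetic model
    generator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
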