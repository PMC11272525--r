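Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for First-Line
    Squamous NSCLC Immunochemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) partitioned
    survival model comparing camrelizumab plus paclitaxel and carboplatin
    against sintilimab plus gemcitabine and platinum as first-line treatment
    of advanced squamous non-small-cell lung cancer, from the Chinese payer
    perspective. Provides Weibull survival extrapolation of digitized
    Kaplan-Meier curves (maximum likelihood on pseudo individual-patient
    data and complementary-log-log regression on curve coordinates),
    hazard-ratio adjustment of comparator curves under proportional
    hazards, fixed-effect graph-theoretical network meta-analysis of
    trial-level log hazard ratios, discounted accrual of life-years,
    quality-adjusted life-years and costs, incremental cost-effectiveness
    ratios, one-way deterministic sensitivity analysis (tornado), and
    seeded Monte-Carlo probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves. A synthetic-data module
    generates pseudo individual-patient data, digitized curve coordinates
    and trial-level hazard-ratio tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    flexsurv,
    survival,
    optparse
Config/testthat/edition: 3
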