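Package: mdtcea
Title: Trial-Based Markov Cost-Utility Analysis of Metastasis-Directed
    Therapy for Oligorecurrent Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-state Markov cohort model comparing metastasis-directed
    therapy (MDT) with delayed androgen-deprivation therapy (ADT), surveillance
    with delayed ADT, and immediate ADT for oligorecurrent prostate cancer,
    from a healthcare payer's perspective. Implements monthly cycles with
    half-cycle correction and differential discounting of costs and effects,
    life-table background mortality with a prostate-cancer-death adjustment,
    incremental cost-effectiveness (ICER) and net-monetary-benefit arithmetic,
    probabilistic sensitivity analysis with moment-matched gamma and beta
    distributions, cost-effectiveness acceptability curves, one-way tornado
    analysis, cost-threshold inversion, effect-size scaling and standard-error
    scenario scans.  Ships synthetic parameter presets, including a base-case
    preset built from the published trial summaries with flagged placeholder
    values for appendix-only quantities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
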