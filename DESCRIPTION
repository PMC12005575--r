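Package: pdtsim
Title: Discrete Event Simulation of Post-Donation Hemoglobin Testing Strategies for Whole Blood Donors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level discrete event simulation of whole-blood donor
    attendance in England under the current on-session hemoglobin screening
    strategy and four stratified post-donation-testing (PDT) strategies.
    Provides a synthetic donor-cohort generator, sex-specific linear mixed
    models for hemoglobin recovery after donation, flexible parametric
    (Royston-Parmar) survival models for invitation-to-attendance delay,
    strategy rule encodings (hemoglobin categories, on-session test
    triggering, reinvitation intervals), a per-donor event-loop simulator
    with common random numbers, and an evaluation layer: per-1000-donor
    event tables, cost per donation, donation-equivalent utilities,
    probabilistic sensitivity analysis with percentile uncertainty
    intervals, and national projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    flexsurv,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
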