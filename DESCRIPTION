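Package: wcr
Title: Inverse Probability of Treatment Weighted Competing Risks Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the cumulative incidence of an event of
    interest in the presence of competing events while adjusting for measured
    confounding by inverse probability of treatment (IPT) weighting.
    Implements stabilized, truncated propensity weights with covariate balance
    diagnostics; weighted and unweighted Kaplan-Meier survival, the naive
    Kaplan-Meier cumulative incidence obtained by censoring competing events,
    and the Aalen-Johansen competing-risks cumulative incidence estimator;
    weighted cause-specific Cox proportional hazards regression with robust
    (sandwich) variance; subject-level bootstrap confidence intervals; and a
    synthetic multi-arm cohort simulator with confounded treatment assignment
    and closed-form true cumulative incidence for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    nnet,
    stats,
    utils
Suggests:
    cmprsk,
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
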