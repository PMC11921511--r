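Package: amhref
Title: Age-Specific AMH Reference Ranges and PCOS Prevalence Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives age-specific serum anti-mullerian hormone (AMH)
    reference percentiles from cross-sectional cohort data and estimates
    polycystic ovary syndrome (PCOS) prevalence with a two-of-three
    criterion rule (oligo-/amenorrhea, hyperandrogenemia by free androgen
    index, AMH above a reference percentile). Includes deterministic
    biomarker derivation (SI conversion, limit-of-detection substitution,
    free androgen index, HOMA-IR, Polynesian BMI classes), an eligibility
    filter with an exclusion ledger, polynomial models of the log10 AMH
    age trajectory selected by adjusted R-squared, descriptive and
    bivariate statistics, and a seeded synthetic-cohort generator that
    emulates the statistical structure of a Samoan cohort study so the
    whole pipeline is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
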