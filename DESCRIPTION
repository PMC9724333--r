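Package: hbdesign
Title: Hemoglobin-Based Observational Study Design for Transfusion Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building hemoglobin-based observational studies of
    perioperative red-blood-cell transfusion. Implements construction of base
    and study populations from perioperative records, extraction of per-patient
    transfusion trigger values (last measurement before the initial transfusion
    for transfused patients, in-stay nadir for controls), standardized mean
    difference balance diagnostics, propensity-score nearest-neighbor caliper
    matching, and adjusted logistic odds-ratio estimation across the four
    analysis datasets (base and study populations, each before and after
    matching). Includes a seeded synthetic perioperative cohort generator that
    reproduces the confounding-by-indication structure of transfusion practice
    so the full pipeline can be exercised and validated without access to
    confidential patient data.
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
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
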