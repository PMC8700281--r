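Package: ctdnascreen
Title: Detection Limits and Screening Performance of Circulating Tumor DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysical modelling of circulating tumor DNA (ctDNA) for
    early-cancer screening feasibility. Chains tumor size to mutant allele
    fraction (MAF) and to the expected number of tumor genome copies in a
    blood draw, derives Poisson sampling limits of detection (minimum
    detectable tumor diameter and MAF), computes analytic screening
    performance (PPV, NPV, expected confusion counts) under configurable
    sensitivity, specificity and prevalence, and validates the analytic
    results with a seeded Monte Carlo cohort simulator. Reference scenarios
    and tumor-characteristics tables are packaged as machine-readable data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
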