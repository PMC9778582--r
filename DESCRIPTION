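Package: bphpersist
Title: Medication Persistence and Drug Survival Analysis for BPH/BPO Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for measuring persistence to alpha-1-adrenoceptor
    antagonists (ABs) and steroid 5-alpha-reductase inhibitors (5ARIs) from
    pharmacy dispensing records: record validation and I/O, new-user cohort
    selection with wash-out and chronic-use filters, construction of treatment
    episodes under per-dispensation grace periods, Kaplan-Meier drug survival
    with Greenwood variance and log-rank comparisons, and drug co-prescription
    network summaries. Includes a seeded synthetic claims generator with known
    ground truth so every stage is testable without access to administrative
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
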