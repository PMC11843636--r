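Package: pvscreen
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance screening pipeline for FAERS-style spontaneous
    adverse-event report databases: parsing of quarterly dollar-delimited raw
    tables (DEMO, DRUG, REAC, OUTC), FDA-style case deduplication, primary-suspect
    cohort selection, reporting odds ratio (ROR) and proportional reporting ratio
    (PRR) disproportionality screening at preferred-term and system-organ-class
    level, novel-signal filtering against configurable exclusion lists, a
    five-dimension clinical-priority rubric, and sex/age subgroup comparison.
    Includes a seeded synthetic report-database generator with injected
    drug-event signals so the whole pipeline is testable without a FAERS
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
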