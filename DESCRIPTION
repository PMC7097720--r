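Package: rxmatch
Title: Automated Double-Check of Medication Selection in Outpatient Pharmacies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects potential medication selection errors made when outpatient
    pharmacies transcribe electronic prescriptions. Both the prescribed and the
    dispensed National Drug Code (NDC) are normalized to the 11-digit 5-4-2
    form, resolved to semantic clinical drug (SCD) concepts through a drug
    terminology backend (the public RxNorm REST API or a local fixture store),
    and matched; mismatches are classified by clinical significance (different
    ingredient, strength, pack quantity, dose form, qualitative distinction,
    or concept outside the curated terminology) and aggregated into error
    matrices with accuracy, sensitivity, false-positive rate, specificity,
    precision and F1 for both static (total-pair) and learning (unique-pair)
    alerting modes. Includes a deterministic synthetic terminology and
    record-pair generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
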