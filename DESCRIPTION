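Package: cinvaudit
Title: Claims-Based Audit of Chemotherapy Emetic Risk and Antiemetic Prophylaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing chemotherapy-induced nausea and vomiting (CINV)
    risk and prophylactic antiemetic prescribing in administrative claims data
    linked to a cancer registry. Builds a first-course chemotherapy cohort with
    reproducible inclusion/exclusion logic, assembles 8-day combination
    regimens, classifies their emetic risk under the JSCO, ASCO, NCCN and
    MASCC/ESMO guideline systems from packaged rule tables (including
    dose-per-body-surface-area tiers and named combination overrides such as
    FOLFIRINOX and anthracycline plus cyclophosphamide), attributes antiemetic
    claims to the first course with same-day and 30-day oral lookback windows,
    and tabulates stratified proportions with exact binomial confidence
    intervals. A synthetic linked registry-plus-claims generator with known
    ground truth supports end-to-end validation without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
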