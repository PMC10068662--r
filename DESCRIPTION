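Package: periopdw
Title: Perioperative Data Warehouse: Synthetic Sources, Incremental ETL,
    Intraoperative Features, OMOP Export and Federated Logistic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale anesthesia data warehouse. Generates synthetic
    anesthesia-information-management-system (AIMS) and hospital-discharge
    (PMSI-like) source extracts with ground truth, mirrors and transforms
    them (record linkage, vocabulary cleaning, unit conversion, quality
    flagging), loads a normalized warehouse through two incremental
    sliding-window flows, computes per-intervention intraoperative features
    (summary statistics and threshold-episode burden such as time below a
    mean-arterial-pressure threshold and area under the threshold), pivots
    features into wide datamarts and cohort tables, runs four-axis data
    quality checks (completeness, correctness, concordance, plausibility),
    exports OMOP CDM v5.4 shaped tables, and fits logistic regression across
    horizontally split centers by exchanging only per-center gradients and
    information matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
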