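Package: pdmsetl
Title: Governed Extraction, Transformation and Export of Intensive Care
    PDMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A governance-first ETL toolkit for intensive-care patient data
    management system (PDMS) records. Provides read-only relational source
    access with bounded identifier batching, reconstruction of continuous
    therapy/device episodes from fragmented interval documentation,
    medication concentration reconstruction and dose-rate standardization,
    schema-contract validation with plausibility bounds, salted irreversible
    pseudonymization, structured JSON-lines audit logging, and
    analysis-ready CSV/Parquet export. Ships a seeded synthetic PDMS
    generator with retained ground truth so every pipeline stage is testable
    without access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    arrow,
    digest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
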