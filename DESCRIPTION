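Package: cocmbill
Title: Billing Eligibility and Reimbursement Potential for Collaborative Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the reimbursement potential of Collaborative Care Model
    (CoCM) and general Behavioral Health Integration (BHI) billing codes
    applied to a care-management registry. Aggregates per-encounter registry
    records into patient calendar months, evaluates CoCM/BHI service
    requirements, assigns billing codes under CPT half-plus-one time rules
    with code precedence and initial-code deferral, prices decisions against
    a fee schedule, and summarizes billable and unbillable minutes, revenue
    per hour of care management, ineligibility taxonomies, and sensitivity
    scenarios. Includes a seeded synthetic registry generator so every stage
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
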