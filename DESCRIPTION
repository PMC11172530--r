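Package: melpathsim
Title: Clinical Pathway Simulation and Data-Completeness Evaluation for Stage III Melanoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the treatment of stage III melanoma patients step by
    step along an SOP-derived clinical algorithm with 27 decision points.
    Reads FHIR-style JSON patient bundles, extracts the 16 decision-relevant
    clinical parameters, traverses a declaratively configured pathway graph
    recording a full execution trace per patient, and aggregates cohort-level
    pass counts with flow-conservation checks. A seeded synthetic-cohort
    generator reproduces the study cohort's baseline marginals so the whole
    pipeline runs without restricted patient data. Survey-based evaluation
    utilities classify per-parameter relevance, compute per-decision-point
    data-completeness rates (with and without implicitly used parameters),
    and score the concordance of simulated next treatment steps against
    clinician survey responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    data.table,
    igraph,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
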