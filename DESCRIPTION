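Package: psnstrat
Title: Patient Stratification from Symptom-Coded Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("PSN", "Maintainers", email = "maintainers@psnstrat.org", role = c("aut", "cre"))
Description: Stratifies inpatient cohorts from symptom-coded electronic
    medical records. Curates admission records against a term-normalization
    dictionary, builds a shared-symptom patient similarity network from
    Jaccard set similarity (thresholded chief-complaint network overlapped
    with a history-of-present-illness network), detects patient subgroups by
    weighted Louvain modularity maximization or by an overlapping
    cluster-affiliation model, characterizes subgroups by relative-risk
    enrichment of symptoms, tongue and pulse features, diagnoses and herbs
    with chi-square screening, and scores per-subgroup symptom resolution
    between admission and discharge. Ships a synthetic-cohort generator with
    planted subgroups so every stage is testable without access to hospital
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
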