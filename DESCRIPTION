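Package: praxnet
Title: Information-Exchange Network Analysis for Primary-Care Practice Teams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for sociometric roster studies of information exchange in
    small primary-care practice teams. Builds directed per-condition
    nomination networks (type 2 diabetes, coronary heart disease, chronic
    heart failure) from roster-questionnaire data, validates reported ties
    with a cohort-level reciprocity gate, symmetrizes networks with
    reconstruction of a single non-respondent's ties, and applies the
    standard inclusion filter (at least three members, at most one
    non-respondent). Computes native network metrics (number of connections,
    density, Freeman degree centralization, reciprocity), classifies each
    network into a four-type density/centralization typology, and provides
    cohort-level statistics (per-condition summaries, tie-corrected Friedman
    rank test, Spearman correlation, external-exchange tabulations). A
    seeded synthetic-cohort generator with tunable tie probability, hub
    bias, reciprocation and non-response makes every pipeline stage testable
    without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
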