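Package: targetAE
Title: Target-Level Phenotype Profiling from Adverse-Event Case Reports
Version: 0.1.0
Authors@R: person("Analytics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Drug-centric integration of spontaneous adverse-event case
    reports with drug-target knowledge, and disproportionality analysis of
    the resulting target-phenotype co-occurrences.  Normalizes verbatim
    drug-mention strings against a synonym dictionary (exact, token-part and
    bounded edit-distance matching with a blacklist), expands mapped drugs to
    targets, metabolizing enzymes, transporters, pathways and ATC classes,
    and characterizes entity-event associations with the proportional
    reporting ratio (PRR), Fisher's exact test and Benjamini-Hochberg
    q-values.  Includes cohort outcome comparison, temporal slicing for
    prospective prediction, a benchmark module contrasting direct
    target-level signals with indirect drug-mediated signals, and a
    synthetic-data generator that emulates FAERS-like corpora with planted
    target-reaction effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
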