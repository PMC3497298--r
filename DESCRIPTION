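Package: pdbtriage
Title: Triage of 'Unknown Function' Protein Structure Entries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic, auditable triage of Protein Data Bank entries
    annotated as proteins of unknown function. Each entry passes through
    four stages: annotation sufficiency against its mapped sequence-database
    record, sequence-homology evidence filtered with Gene Ontology
    domain-specific identity cutoffs, structural-homology evidence banded by
    alignment Z-score, and deposition-date provenance. The result is a
    funnel report separating true uncharacterized proteins from
    re-annotation candidates, with every stage count and percentage
    recomputed from the per-entry verdicts. A seeded synthetic corpus
    generator produces fixture corpora with exact, pre-specified class
    counts so the whole pipeline can be exercised end to end without any
    database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
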