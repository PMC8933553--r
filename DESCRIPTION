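Package: trialgraph
Title: Knowledge Graphs from Clinical-Trial Registry Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a heterogeneous knowledge graph from AACT-style
    relational exports of a clinical-trial registry. Studies are filtered to
    those with drug interventions, conditions and outcome analyses; adverse
    events, drug mentions, statistical-method names and outcome measures are
    normalized with deterministic rule cascades (parenthetical stripping,
    auxiliary-phrase removal, stop-word removal and lemmatization,
    edit-distance rescue, abbreviation mining, TF-IDF clustering); the result
    is assembled into a typed graph of 18 node types and 21 relation types
    with schema validation, statistics and tab-separated export. Translational
    (TransE) embeddings trained on the graph support similarity retrieval and
    drug-repurposing candidate ranking. A seeded synthetic-fixture generator
    emulates registry tables and dictionaries so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
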