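Package: eventstack
Title: Biomedical Event Extraction with Stacked Model Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biomedical event extraction in the BioNLP shared-task
    setting: reading and writing standoff annotation (.txt/.a1/.a2), conversion
    between event structures and labeled token graphs, a joint extractor with
    dual-decomposition inference and MIRA learning, an edge-factored dependency
    parser with projective and non-projective decoders used as a stacked input,
    set-theoretic model combination (union, intersection), event-origin analysis
    with novel-event filtering, non-projectivity analysis, BioNLP-style event
    matching and scoring, and a calibrated synthetic-corpus generator so the
    whole pipeline runs without licensed corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
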