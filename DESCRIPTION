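Package: clinrag
Title: Knowledge-Graph Retrieval-Augmented Generation for Clinical Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Augments a pluggable multiple-choice answer backend with clinical
    knowledge retrieved from a semantic-triple knowledge graph. Provides a
    triple store with typed relations and a curated relation allow-list, a
    deterministic lexicon-based concept tagger, graph embeddings (biased
    random walks with skip-gram) and knowledge-graph embeddings (TransE,
    RotatE) with cosine-similarity search, context assembly that verbalizes
    retrieved triples into human-readable sentences, a rule-based mock answer
    backend for model-free testing, and a paired evaluation protocol
    (confabulation rate, exact Cochran Q test with question blocks). Includes
    generators for synthetic knowledge graphs, lexicons, and exams with
    planted answerable facts so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
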