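Package: relclass
Title: Relation Classification to Complement Rule-Based Biomedical Triple Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds relation-classification corpora from triple-annotated
    sentence collections (bidirectional expansion, hard-negative generation,
    semantic-type and semantic-group entity substitution, entity-marker
    insertion), trains an entity-marker sequence classifier with optional
    contrastive pre-training over augmentation-generated positive pairs,
    calibrates per-class decision thresholds on validation predictions,
    evaluates against a rule-based extractor (precision/recall/F1, one-vs-rest
    AUC, McNemar's paired test, overlap decomposition), and runs a large-scale
    expansion pipeline that proposes new subject-predicate-object predications
    from SemMedDB-style sentence, entity and predication tables. Includes a
    seeded synthetic-data generator so every stage runs without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
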