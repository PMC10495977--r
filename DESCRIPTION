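Package: rehabspan
Title: Span-Based Named Entity Recognition for Chinese Rehabilitation-Medicine Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for span-based named entity recognition in Chinese
    rehabilitation-medicine text. Provides span-annotated corpus input/output
    (a JSON dialect and BIO-tagged files) with validation and deterministic
    splitting, inter-annotator agreement and entity-frequency statistics, a
    per-category start/end boundary-prediction head with sigmoid pair matching
    that decodes nested entities, a composite boundary + span loss, a training
    loop over a pluggable token encoder with warmup scheduling and
    self-training augmentation, entity-level precision/recall/F1 evaluation
    with a cross-validation harness and a softmax BIO baseline, and a
    seed-deterministic synthetic-corpus generator with controllable nesting
    and low-frequency-entity proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
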