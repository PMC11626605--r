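Package: housenlp
Title: Rule-Based Extraction of Housing Instability Concepts from Clinical Notes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A lightweight rule-based clinical natural language processing
    engine for identifying housing instability and homelessness in
    unstructured clinical notes. Ships a six-concept housing lexicon compiled
    to flexible word-boundary-anchored patterns, a deterministic clinical
    sentence segmenter with exact character offsets, a dictionary matcher,
    a ConText-style assertion classifier (negation, historical, experiencer)
    with sentence-bounded scopes, note-level positive/negative labeling,
    an evaluation harness with an error taxonomy, and a template-based
    generator of labeled synthetic emergency-department notes for end-to-end
    benchmarking without any protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
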