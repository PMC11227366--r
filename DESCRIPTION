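Package: sigcr
Title: Signature-Based Dictionary Concept Recognition for Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dictionary-based concept recognition for ontologies such as the
    Human Phenotype Ontology. Ontology term labels and synonyms are reduced to
    order-free "signatures" over clusters of morphologically equivalent tokens,
    enabling linear-time annotation of free text with ontology concepts that is
    robust to inflection, derivation, word order, and localized spelling
    variants. Includes OBO and obographs-JSON readers, a deterministic
    morphological clusterer with a pluggable stemmer, document- and
    mention-level precision/recall/F1 evaluation, corpus alignment of retired
    concept identifiers via alt_id, and a synthetic fixture generator for
    fully self-contained testing.
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
    withr
Config/testthat/edition: 3
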