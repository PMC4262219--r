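Package: patrex
Title: Trigger-Driven Pattern-Based Biomedical Relation Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based framework for extracting biomedical events
    (phosphorylation, gene expression, binding, and similar relations)
    from text. Starting from a declarative trigger specification -- a verb
    root, a subcategorization frame, per-argument semantic type constraints
    and role assignments -- the package derives surface trigger forms by
    morphological rules, instantiates a fixed inventory of lexico-syntactic
    pattern templates, and matches them over Penn Treebank constituency
    parses with a small tree-pattern language. Sentence simplification
    (coordination splitting, relative clause extraction, apposition and
    parenthetical substitution, attachment alternatives) exposes clauses
    that the simple patterns can match, and referential relation linking
    (part-whole, member-collection, hyponymy, apposition, relative-pronoun
    coreference) rewrites arguments that are not informative named
    entities. Events are read and written in BioNLP-ST standoff format and
    scored with the approximate recursive matching metric. A synthetic
    document generator produces text, gold parses, entity annotations and
    gold events for end-to-end testing without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
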