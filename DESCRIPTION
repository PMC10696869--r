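Package: rdfqa
Title: Foundational Quality Assessment of RDF Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses RDF resources (ontologies, vocabularies, metadatasets)
    against six foundational, objective quality metrics covering resolvability,
    parsability, and consistency: non-resolvable URIs, non-parsable URIs,
    undefined URIs, misplaced classes or properties, misuse of
    owl:DatatypeProperty or owl:ObjectProperty, and use of deprecated classes
    or properties. Every unique URI of a document is dereferenced with
    RDF-preferring content negotiation (offline fixture maps supported for
    fully reproducible runs), cascaded through a verdict pipeline, and the
    resulting per-metric error sets are serialized as machine-readable Data
    Quality Vocabulary (DQV) assessment reports in Turtle. Bundled SPARQL
    queries answer quality questions over collections of reports. A synthetic
    fixture forge generates RDF resources with controlled error injections and
    an exact expected-result ledger, so the whole pipeline is testable with no
    network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
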