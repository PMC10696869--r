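---
title: "Assessing RDF resource quality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing RDF resource quality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdfqa)
```

## The assessment model

`rdfqa` measures foundational quality of an RDF document: not whether its
modelling is good, but whether the machinery of linked data works at all.
Three dimensions are covered by six metrics.

**Resolvability.** Every unique URI of the document (collected from all
three triple positions, deduplicated by exact string equality) is
dereferenced by HTTP GET. The request carries an Accept header listing the
RDF media types (`text/turtle`, `application/x-turtle`, `text/plain` as
N-Triples, `application/ld+json`, `text/n3`, `application/rdf+xml`) at the
highest factor weighting and `*/*` at the lowest (`q=0.1`), so a server
returns RDF whenever it can and anything else only as a fallback. A final
status of 4xx or 5xx means non-resolvable; 1xx–3xx-terminating chains are
resolvable. Network failures (DNS, timeout) map to a sentinel status 0 and
count as non-resolvable, as do non-`http(s)` schemes (`urn:`, `mailto:`)
and malformed URIs, each with a distinct reason code so reports can be
filtered. We record HTTP 423 (Locked) like any other client error — it is
how access-controlled terminology servers answer bulk dereferencing, and
downstream consumers are equally unable to retrieve definitions — but the
status code is preserved in the verdict so such rows can be set aside as a
special case, as the published rare-disease assessment did for SNOMED CT.

**Parsability.** For resolvable URIs whose media type (lowercased,
parameters such as `charset` stripped) is an RDF type, the body is parsed
with the parser *declared by the media type* — no content sniffing on
mismatch, because the metric is about the server's declaration. Content
yielding fewer than one triple (including empty-but-valid documents) is
non-parsable. Two deliberate consequences: Turtle served as
`application/rdf+xml` is non-parsable, and plain prose served as
`text/plain` is non-parsable because `text/plain` maps to N-Triples and the
N-Triples parser is strict. Resolvable URIs with a *non*-RDF media type
(`text/html`, a PDF, ...) are **not errors**: the server honestly signals
that no RDF representation exists, and the URI simply leaves the cascade at
the `non_rdf_content` stage.

**Definedness.** A parsable URI is *defined* iff the exact URI string
occurs in any position of at least one retrieved triple. Matching is
purely syntactic: a URI with a trailing `#` does not define its hashless
variant, and `...dc/elements/1.1/license` is not defined by the existence
of `...dc/terms/license`. This reproduces the behaviour of pattern-matching
assessment (including its known harshness: an ontology URI whose document
only mentions the `#`-suffixed form counts as undefined — the verdict
`detail` field carries a human-readable explanation for auditing). A
stricter subject-only mode (`subject_only = TRUE`) is available for
comparison; the any-position default follows the metric's definition,
which asks whether the URI *exists within* the parsed triples, not whether
it is a subject.

**Consistency.** Defined URIs are typed *from their definition graphs
only* (never from the assessed document): classes are terms typed
`owl:Class` or `rdfs:Class`; properties are terms typed `rdf:Property` or
any OWL property type. Four rule families follow:

* *Misplaced classes* — a class in the predicate slot of any document
  triple.
* *Misplaced properties* — a property in the object slot, unless the
  triple's predicate is a defining predicate (default: `rdf:type`,
  `rdfs:subPropertyOf`, `owl:onProperty`, `owl:equivalentProperty`,
  `owl:inverseOf`, `owl:propertyDisjointWith`, `rdfs:seeAlso`,
  `dcterms:relation`). The exception list is inherently open-ended ("such
  as"), so it is a visible, overridable argument.
* *Flavor misuse* — for properties in their correct role (the predicate
  slot): a datatype property whose object is a URI, or an object property
  whose object is a literal. Blank-node objects are neither URIs nor
  literals and trigger neither rule. Annotation properties carry no OWL
  range discipline and are exempt.
* *Deprecation* — a term is deprecated iff its definition graph contains
  `T owl:deprecated "true"^^xsd:boolean`, `T rdf:type owl:DeprecatedClass`,
  or `T rdf:type owl:DeprecatedProperty`. An untyped `"true"`, a `"false"`,
  or a capitalized `"True"` does not deprecate. Any document occurrence of
  a deprecated term is a use; deprecated terms remain subject to the other
  consistency rules.

Terms typed `owl:NamedIndividual` (and not also class/property) are
instance-level: only resolvability and parsability apply to them, so they
are exempted from the consistency rules and excluded from the
class/property denominators. A term punned as both class and property is
evaluated under both rule families.

## Metric results and denominators

Each metric reports distinct erroneous URIs (numerator), a denominator, and
the count of document triples containing at least one erroneous URI
("affected triples"). The URI-level metrics use all unique URIs as
denominator. The metric definitions state misplacement and deprecation as
two parallel proportions (over classes, over properties); since one
measurement node carries one value, we report a single headline fraction
with denominator = unique classes + unique properties *among the
document's defined URIs*, and keep the class/property split in the error
kinds. Flavor misuse uses all unique properties, which is consistent with
the published per-resource property denominators (19 for the WikiPathways
ontology, 88 for HPO). Whether "all unique classes" means classes used in
the assessed document or classes defined anywhere is not specified by the
metric table; we use the document's defined URIs, the reading under which
the published property denominators come out right. A zero denominator
yields a defined `0/0` result with a 0% proportion.

Percentages are formatted at one decimal place, as assessment tables print
them, using standard rounding (`sprintf("%.1f")`). Note that a few cells of
the published sixteen-resource table were evidently truncated rather than
rounded (e.g. 53/15,070 printed as 0.3% where one-decimal rounding gives
0.4%, and 356,523/356,548 printed as 99.9%); our formatter does not
reproduce truncation, and internal threshold comparisons never use the
formatted string — the `>10%` filter in the bundled query compares
`10 × numerator > denominator` in exact integer arithmetic, which is exact
for all counts below 2^53.

## Reports and quality questions

A report types the resource `dcat:Resource` and links one
`dqv:QualityMeasurement` node per metric via `dqv:hasQualityMeasurement`;
each measurement carries `dqv:isMeasurementOf` (the metric URI),
`dqv:value` (the lexical fraction `"n/N"`), `prov:generatedAtTime` (an
`xsd:dateTime`; fix `generated_at` for byte-reproducible reports), and one
`dcterms:relation` link per erroneous URI. Measurement nodes are URIs
derived from the resource identifier, so reports are ground graphs and
round-trip through Turtle by set equality. By default passed metrics keep
`"0/N"` measurements so "which metrics were tested" stays queryable;
`failures_only = TRUE` reproduces the published report layout that shows
only failing metrics. The metric vocabulary (`http://purl.org/fqm#`) names
the non-resolvable and undefined metrics; the other four identifiers follow
the same naming style behind a remappable argument (`fqm_metric_uris()`) so
they can be aligned with the vocabulary without code change.

Three SPARQL questions ship as `.rq` files (resources over 10%
non-resolvable; resources with undefined URIs and which; the issues,
metrics, and metric definitions for one resource). They run over the union
of report graphs and the metric-descriptor graph in the package's SPARQL
SELECT subset engine — basic graph patterns plus FILTER with string and
integer builtins — which is deliberately minimal; any SPARQL 1.1 endpoint
can be used instead by loading the Turtle reports.

## The fixture forge: what it emulates, and what it does not

`forge_spec()`/`forge_resource()` generate a synthetic resource plus a
matching offline fixture map and an exact expected-result ledger. Three
scaffold URIs (an anchor individual, a well-defined object property, a
well-defined datatype property) support witness and filler triples; every
injected error category materializes the corresponding metric condition
exactly (404 entries, garbage bodies behind RDF media types, definition
graphs omitting the requested URI, mistyped usage triples, the deprecation
patterns alternating between the boolean flag and the Deprecated* typing).
Injections are placed before filler; the URI-to-category assignment is a
pure function of the seed; identical specs give byte-identical Turtle.
Filler never touches injected URIs, so each error URI occurs in exactly one
witness triple, and scaffold properties never occupy object slots (which
would fabricate misplacement errors).

The forge emulates *error structure*, not ontology topology: real
vocabularies have deep class hierarchies, imports, annotations in many
languages, hash-URI families sharing one large document, and servers with
redirect chains and content-negotiation quirks. Passing the ledger tests
therefore demonstrates that the assessor implements the metric definitions
exactly on controlled inputs; it does not demonstrate robustness to every
real-world serving configuration (hash-URI sharing, redirect handling, and
media-type edge cases are covered by targeted unit tests instead). Default
sizes in the test suite are desk-scale by design — tens to a few hundred
URIs per forged resource, fifty seeds for ledger recovery, one thousand
miniature fixtures for the cascade-partition property — chosen to exercise
every code path many times over while keeping a full run in a few minutes.

The published sixteen-resource assessment itself is *not* reproducible
live (the web has moved on since 2022-12-30, which is precisely the
dynamic-resource problem the metrics address), so the package stores its
printed error counts (`published_assessment_counts()`) and rebuilds DQV
reports from them (`replay_published_counts()`) with synthetic placeholder
error URIs; the replayed reports reproduce the published aggregate query
answers (five resources over the 10% threshold with the access-blocked
SNOMED CT row excluded per its special-case footnote; 69 undefined-URI
rows; three failed metrics for the WikiPathways ontology).

## Numerical and implementation choices

* **Inventory conventions.** Literals are counted as occurrences (one per
  object slot), not deduplicated — this matches the magnitudes of the
  published per-resource literal counts, though deduplication is not
  explicitly specified there. Blank nodes are counted as distinct labels.
  Blank nodes never enter metric denominators.
* **Caching.** Outcomes are cached per defragmented request URI: hash URIs
  sharing a namespace document cost one fetch and one parse, which is what
  makes assessing hash-heavy ontologies feasible; a `resolution_cache()`
  can be shared across runs, making re-classification fetch-free.
* **Retries.** 5xx, 429, and transport failures are retried (default 3
  attempts) with exponential backoff (`backoff * 2^(attempt-1)`); 4xx is
  never retried. Offline runs use `backoff = 0`.
* **Parsers.** The package implements its own RDF layer (no RDF stack
  exists on CRAN/Bioconductor in this environment): a full-featured Turtle
  reader (prefixes, bases, blank-node property lists, typed/tagged
  literals, numeric/boolean shorthand; RDF collections `( ... )` are
  rejected with a clear error), a strict line-based N-Triples reader, an
  RDF/XML reader over `xml2` (about/ID/nodeID, typed nodes, property
  attributes, `parseType="Resource"`, datatypes and language tags), and a
  JSON-LD reader over `jsonlite` (inline contexts with prefix/term maps,
  `@graph`, `@id`/`@type`/`@value`/`@language`; remote contexts and
  `@list` are rejected). Notation 3 is parsed as Turtle. Parser fidelity is
  cross-checked in the test suite against an independent RDF
  implementation on shared fixtures.
* **Degenerate inputs.** Empty documents yield zero inventories and six
  `0/N` (or `0/0`) results; documents whose URIs all fail resolution yield
  empty consistency denominators rather than errors.
* **Determinism.** The forge seeds a local RNG stream and restores the
  caller's `.Random.seed`; reports are deterministic given `generated_at`.

## Limitations

Full OWL reasoning (disjointness violations, unsatisfiability) is out of
scope — the metrics are deliberately syntactic and foundational. Named
graphs (TriG/N-Quads) are not read. The SPARQL engine implements only the
subset the quality queries need. Live transport shells out to `curl` and
does sequential fetching; assessing multi-million-triple terminologies is
possible in principle (documents are held in memory as tibbles) but the
package is tuned for desk-scale vocabularies and metadatasets.
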