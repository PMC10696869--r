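# rdfqa — foundational quality assessment of RDF resources

Biomedical knowledge is increasingly published as linked data: ontologies,
vocabularies, schemas, and metadatasets represented in the Resource
Description Framework (RDF), where every term is a URI and every statement a
subject–predicate–object triple. The promise — that any term can be
dereferenced to a machine-readable definition and connected to other
resources — only holds when the URIs actually resolve, the retrieved content
actually parses, and the terms are used consistently with their definitions.
In practice they often are not: URIs 404, namespaces get misspelled
(`dc/elements/1.1/license` vs `dc/terms/license`), hash and hashless variants
get confused, and `owl:ObjectProperty` predicates end up pointing at quoted
strings instead of resources. In scarce-data domains such as rare diseases,
where interoperability between scattered registries, biobanks, and
ontologies matters most, these foundational defects silently break the
linked-data value chain.

`rdfqa` assesses any RDF document against six objective, automatable quality
metrics spanning three dimensions:

| Dimension     | Metric | Definition (numerator / denominator) |
|---------------|--------|--------------------------------------|
| Resolvability | Non-resolvable URIs | URIs whose dereferencing ends in an HTTP 4xx/5xx error / all unique URIs |
| Parsability   | Non-parsable URIs | URIs served with an RDF media type whose content yields no RDF triple / all unique URIs |
| Parsability   | Undefined URIs | URIs absent from the triples obtained by resolving them / all unique URIs |
| Consistency   | Misplaced classes or properties | classes used as a predicate, or properties used as an object outside defining triples / unique classes + properties |
| Consistency   | Misuse of owl:DatatypeProperty / owl:ObjectProperty | datatype properties with a URI object, or object properties with a literal object / unique properties |
| Consistency   | Use of deprecated classes or properties | deprecated terms in use / unique classes + properties |

Every unique URI is dereferenced once (fragments stripped for the request,
verdicts recorded per full URI) with an RDF-preferring `Accept` header, and
cascaded to exactly one verdict: `non_resolvable`, `non_rdf_content` (not an
error — the server is honestly saying it has no RDF), `non_parsable`,
`undefined`, or `defined`. Defined terms are then typed from their
definition graphs and checked by the consistency rules. Results are
serialized as a [Data Quality Vocabulary](https://www.w3.org/TR/vocab-dqv/)
(DQV) report in Turtle, and bundled SPARQL queries answer quality questions
over collections of reports.

Everything runs offline against *fixture maps* (canned HTTP responses), and
a **fixture forge** generates synthetic resources with exact, ledgered error
injections in every category — so the whole pipeline is testable with no
network. Live assessment over HTTP is an optional mode.

The package is tidyverse-native: graphs are tibbles of triples, results are
tibbles, assessments support `tidy()`, `glance()`, and `autoplot()`.

## Worked example

Forge a resource shaped like a small patient-registry metadataset — 54
unique URIs, 10 literals, 47 triples, six URIs injected as non-resolvable —
and assess it against its own fixture map:

```r
library(rdfqa)

spec   <- forge_spec(seed = 1, n_uris = 54, non_resolvable = 6,
                     n_literals = 10, n_triples = 47)
forged <- forge_resource(spec)

a <- rdf_assess(forged$document,
                transport = offline_transport(forged$fixture_map),
                resource_id = "http://example.invalid/resource/registry",
                generated_at = as.POSIXct("2022-12-30", tz = "UTC"))
a
#> RDF quality assessment of <http://example.invalid/resource/registry>
#>   54 unique URIs, 10 literals, 0 blank nodes, 47 triples
#>   Non-resolvable URIs                                  6/54 (11.1%)   affected triples 6/47 (12.8%)
#>   Non-parsable URIs                                    0/54 (0.0%)   affected triples 0/47 (0.0%)
#>   Undefined URIs                                       0/54 (0.0%)   affected triples 0/47 (0.0%)
#>   Misplaced classes or properties                      0/2 (0.0%)   affected triples 0/47 (0.0%)
#>   Misuse of owl:DatatypeProperty or owl:ObjectProperty 0/2 (0.0%)   affected triples 0/47 (0.0%)
#>   Use of deprecated classes or properties              0/2 (0.0%)   affected triples 0/47 (0.0%)
```

Each line is one metric: distinct erroneous URIs over the metric's
denominator, and how many document triples touch at least one of those
URIs. `tidy(a)` returns the same as a tibble (with the error-URI sets as a
list-column); `glance(a)` gives a one-row summary; `autoplot(a)` a bar
chart. The DQV report reproduces the standard layout — one
`dqv:QualityMeasurement` node per metric with the count pair as
`dqv:value` and one `dcterms:relation` link per erroneous URI:

```r
cat(rdf_serialize(report(a, failures_only = TRUE), "turtle"))
#> <http://example.invalid/resource/registry> a dcat:Resource ;
#>     dqv:hasQualityMeasurement <...#measurement-nonResolvable> .
#> <...#measurement-nonResolvable> a dqv:QualityMeasurement ;
#>     dqv:isMeasurementOf fqm:uriNonResolvableMetric ;
#>     dqv:value "6/54" ;
#>     prov:generatedAtTime "2022-12-30T00:00:00Z"^^xsd:dateTime ;
#>     dcterms:relation <http://fixture.invalid/term/t00001>, ... .   # six links
```

Quality questions are asked with SPARQL over report graphs. The reports of
a published 2022 assessment of sixteen rare-disease resources can be
rebuilt from their printed error counts and queried:

```r
counts  <- published_assessment_counts()
reports <- replay_published_counts(counts[!counts$special, ])
run_quality_query(reports, 1)      # resources with >10% non-resolvable URIs
#> # A tibble: 5 x 2   (registry, biobank, hPSCreg, metadata ontology, pathways ontology)
nrow(run_quality_query(replay_published_counts(counts), 2))
#> [1] 69                            # (resource, undefined URI) pairs
```

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "rdfqa.R", package="rdfqa"))') \
  assess --input resource.ttl --offline-map fixtures.json --output report.ttl
```

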