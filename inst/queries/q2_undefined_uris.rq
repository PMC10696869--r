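# Which resources have undefined URIs, and which URIs are they?
# One row per (resource, undefined URI) via the dcterms:relation links of
# the undefined-URIs measurement.
PREFIX dqv: <http://www.w3.org/ns/dqv#>
PREFIX fqm: <http://purl.org/fqm#>
PREFIX dcterms: <http://purl.org/dc/terms/>

SELECT ?resource ?undefinedUri WHERE {
  ?resource dqv:hasQualityMeasurement ?measurement .
  ?measurement dqv:isMeasurementOf fqm:uriUndefinedMetric .
  ?measurement dcterms:relation ?undefinedUri .
}
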