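# Which resources have more than 10% non-resolvable URIs?
# The dqv:value fraction "n/N" is compared in exact integer arithmetic
# (n * 10 > N), so the 10% threshold never suffers float rounding.
PREFIX dqv: <http://www.w3.org/ns/dqv#>
PREFIX fqm: <http://purl.org/fqm#>
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>

SELECT DISTINCT ?resource ?value WHERE {
  ?resource dqv:hasQualityMeasurement ?measurement .
  ?measurement dqv:isMeasurementOf fqm:uriNonResolvableMetric .
  ?measurement dqv:value ?value .
  FILTER (xsd:integer(STRBEFORE(?value, "/")) * 10 > xsd:integer(STRAFTER(?value, "/")))
}
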