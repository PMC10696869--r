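# What quality issues does a resource have, which metrics do they refer to,
# and how are those metrics defined? Failed metrics are those whose
# measurement value has a non-zero numerator; definitions come from the
# skos:definition property of the metric vocabulary.
PREFIX dqv:  <http://www.w3.org/ns/dqv#>
PREFIX skos: <http://www.w3.org/2004/02/skos/core#>
PREFIX xsd:  <http://www.w3.org/2001/XMLSchema#>

SELECT DISTINCT ?metric ?definition WHERE {
  ?resource dqv:hasQualityMeasurement ?measurement .
  ?measurement dqv:isMeasurementOf ?metric .
  ?measurement dqv:value ?value .
  ?metric skos:definition ?definition .
  FILTER (xsd:integer(STRBEFORE(?value, "/")) > 0)
}
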