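# Well-known vocabulary URIs used throughout the assessment pipeline.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
DQV_NS  <- "http://www.w3.org/ns/dqv#"
DCAT_NS <- "http://www.w3.org/ns/dcat#"
DCT_NS  <- "http://purl.org/dc/terms/"
PROV_NS <- "http://www.w3.org/ns/prov#"
SKOS_NS <- "http://www.w3.org/2004/02/skos/core#"
FQM_NS  <- "http://purl.org/fqm#"

RDF_TYPE      <- paste0(RDF_NS, "type")
RDF_PROPERTY  <- paste0(RDF_NS, "Property")
RDFS_CLASS    <- paste0(RDFS_NS, "Class")
RDFS_LABEL    <- paste0(RDFS_NS, "label")
RDFS_SUBPROP  <- paste0(RDFS_NS, "subPropertyOf")
OWL_CLASS     <- paste0(OWL_NS, "Class")
OWL_DEPRECATED       <- paste0(OWL_NS, "deprecated")
OWL_DEPRECATED_CLASS <- paste0(OWL_NS, "DeprecatedClass")
OWL_DEPRECATED_PROP  <- paste0(OWL_NS, "DeprecatedProperty")
OWL_NAMED_INDIVIDUAL <- paste0(OWL_NS, "NamedIndividual")
OWL_OBJECT_PROPERTY   <- paste0(OWL_NS, "ObjectProperty")
OWL_DATATYPE_PROPERTY <- paste0(OWL_NS, "DatatypeProperty")
OWL_ANNOTATION_PROPERTY <- paste0(OWL_NS, "AnnotationProperty")
XSD_BOOLEAN   <- paste0(XSD_NS, "boolean")
XSD_STRING    <- paste0(XSD_NS, "string")
XSD_DATETIME  <- paste0(XSD_NS, "dateTime")

#' OWL property types recognized when typing terms
#'
#' The set of `rdf:type` objects that mark a URI as a property, beyond
#' `rdf:Property`. Open-ended in OWL; this default is overridable wherever
#' term typing is performed.
#'
#' @return Character vector of absolute URIs.
#' @export
owl_property_types <- function() {
  paste0(OWL_NS, c(
    "ObjectProperty", "DatatypeProperty", "AnnotationProperty",
    "FunctionalProperty", "InverseFunctionalProperty", "TransitiveProperty",
    "SymmetricProperty", "AsymmetricProperty", "ReflexiveProperty",
    "IrreflexiveProperty", "OntologyProperty"
  ))
}

#' Predicates that may legitimately take a property as their object
#'
#' A property in the object slot of a triple is a "misplaced property" error
#' unless the triple's predicate is a defining predicate such as `rdf:type`
#' or `rdfs:subPropertyOf`. The set is open-ended by design and can be
#' overridden in [find_misplaced_properties()] / [rdf_assess()].
#'
#' @return Character vector of absolute URIs.
#' @export
defining_predicates <- function() {
  c(RDF_TYPE, RDFS_SUBPROP,
    paste0(OWL_NS, c("onProperty", "equivalentProperty", "inverseOf",
                     "propertyDisjointWith")),
    paste0(RDFS_NS, "seeAlso"),
    paste0(DCT_NS, "relation"))
}

#' Media types recognized as RDF content
#'
#' Mapping between RDF serialization formats and their media types, used for
#' content negotiation and for choosing the parser of retrieved content.
#' `text/plain` is mapped to N-Triples, so non-RDF prose served as
#' `text/plain` is (harshly but faithfully) judged non-parsable.
#'
#' @return A tibble with columns `media_type` and `format`.
#' @export
rdf_media_types <- function() {
  tibble::tibble(
    media_type = c("text/turtle", "application/x-turtle", "text/plain",
                   "application/ld+json", "text/n3", "application/rdf+xml"),
    format = c("turtle", "turtle", "ntriples", "jsonld", "n3", "rdfxml")
  )
}
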