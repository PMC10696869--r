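#' Type the defined URIs of a document
#'
#' For every URI with a `defined` verdict, inspects its retrieved definition
#' graph (never the assessed document) and records whether it is a class
#' (`owl:Class` / `rdfs:Class`), a property (`rdf:Property` or any OWL
#' property type), its property flavor, deprecation status, and whether it
#' is an `owl:NamedIndividual`. Named individuals that are neither classes
#' nor properties are instance-level terms: only the resolvability and
#' parsability metrics apply to them, so they are exempt from the
#' consistency checks.
#'
#' @param verdicts Verdict tibble from [cascade_verdicts()].
#' @param graphs Named list of definition graphs keyed by request URI.
#' @param property_types URIs whose presence as `rdf:type` object marks a
#'   property; default [owl_property_types()] plus `rdf:Property`.
#' @return Tibble: `uri`, `is_class`, `is_property`, `flavor` (one of
#'   `"datatype"`, `"object"`, `"annotation"`, `"other"`, `"none"`),
#'   `deprecated`, `is_named_individual`.
#' @export
type_terms <- function(verdicts, graphs,
                       property_types = c(RDF_PROPERTY, owl_property_types())) {
  defined <- verdicts$uri[verdicts$stage == "defined"]
  rows <- purrr::map(defined, function(u) {
    g <- graphs[[strip_fragment(u)]]
    types <- if (is.null(g)) character() else
      g$object[g$subject == u & g$subject_type == "uri" &
               g$predicate == RDF_TYPE & g$object_type == "uri"]
    is_class <- any(types %in% c(OWL_CLASS, RDFS_CLASS))
    is_property <- any(types %in% property_types)
    flavor <- if (OWL_DATATYPE_PROPERTY %in% types) "datatype"
      else if (OWL_OBJECT_PROPERTY %in% types) "object"
      else if (OWL_ANNOTATION_PROPERTY %in% types) "annotation"
      else if (is_property) "other"
      else "none"
    tibble::tibble(
      uri = u, is_class = is_class, is_property = is_property,
      flavor = flavor,
      deprecated = (is_class || is_property) && check_deprecated(u, g),
      is_named_individual = OWL_NAMED_INDIVIDUAL %in% types)
  })
  dplyr::bind_rows(c(list(tibble::tibble(
    uri = character(), is_class = logical(), is_property = logical(),
    flavor = character(), deprecated = logical(),
    is_named_individual = logical())), rows))
}

#' Is a class or property deprecated in its definition graph?
#'
#' True iff one of the four deprecation triple patterns matches:
#' `T owl:deprecated "true"^^xsd:boolean`, `T rdf:type owl:DeprecatedClass`,
#' or `T rdf:type owl:DeprecatedProperty` (the boolean pattern applies to
#' classes and properties alike). A `"false"` value or an untyped `"true"`
#' literal does not mark deprecation.
#'
#' @param uri Term URI.
#' @param retrieved_graph Its definition graph.
#' @return Logical scalar.
#' @export
check_deprecated <- function(uri, retrieved_graph) {
  g <- retrieved_graph
  mine <- g$subject == uri & g$subject_type == "uri"
  flag <- any(mine & g$predicate == OWL_DEPRECATED &
              g$object_type == "literal" & g$object == "true" &
              !is.na(g$object_datatype) & g$object_datatype == XSD_BOOLEAN)
  typed <- any(mine & g$predicate == RDF_TYPE & g$object_type == "uri" &
               g$object %in% c(OWL_DEPRECATED_CLASS, OWL_DEPRECATED_PROP))
  flag || typed
}

consistency_error_tibble <- function() {
  tibble::tibble(kind = character(), uri = character(),
                 subject = character(), predicate = character(),
                 object = character(), witness = character())
}

consistency_errors_from <- function(kind, uri_col, rows) {
  if (nrow(rows) == 0) return(consistency_error_tibble())
  tibble::tibble(kind = kind, uri = rows[[uri_col]],
                 subject = rows$subject, predicate = rows$predicate,
                 object = rows$object, witness = nt_lines(rows))
}

#' Find classes used in the predicate position
#'
#' A class is misplaced if it occurs as the predicate of any triple of the
#' assessed document. One error row is produced per (class URI, witness
#' triple); deduplicate on `uri` for the metric numerator.
#'
#' @param doc Assessed document (triple tibble).
#' @param typings Tibble from [type_terms()].
#' @return Tibble of errors with witness triples.
#' @export
find_misplaced_classes <- function(doc, typings) {
  classes <- typings$uri[typings$is_class]
  rows <- doc[doc$predicate %in% classes, ]
  consistency_errors_from("misplaced_class", "predicate", rows)
}

#' Find properties used in the object position
#'
#' A property is misplaced if it occurs as the object of a triple, unless
#' the triple's predicate is a defining predicate (terms are legitimately
#' objects of `rdf:type`, `rdfs:subPropertyOf`, and similar defining
#' triples).
#'
#' @param doc Assessed document.
#' @param typings Tibble from [type_terms()].
#' @param defining Predicates exempt from the rule; default
#'   [defining_predicates()].
#' @return Tibble of errors with witness triples.
#' @export
find_misplaced_properties <- function(doc, typings,
                                      defining = defining_predicates()) {
  props <- typings$uri[typings$is_property]
  rows <- doc[doc$object_type == "uri" & doc$object %in% props &
              !doc$predicate %in% defining, ]
  consistency_errors_from("misplaced_property", "object", rows)
}

#' Find owl:DatatypeProperty / owl:ObjectProperty misuse
#'
#' Applies to properties in their correct role (the predicate slot): a
#' datatype property whose object is a URI is misused, as is an object
#' property whose object is a literal. Blank-node objects are neither URIs
#' nor literals and trigger neither rule. Annotation properties carry no
#' range discipline and are exempt.
#'
#' @param doc Assessed document.
#' @param typings Tibble from [type_terms()].
#' @return Tibble of errors with witness triples.
#' @export
find_misused_property_flavors <- function(doc, typings) {
  dt_props <- typings$uri[typings$flavor == "datatype"]
  ob_props <- typings$uri[typings$flavor == "object"]
  dt_rows <- doc[doc$predicate %in% dt_props & doc$object_type == "uri", ]
  ob_rows <- doc[doc$predicate %in% ob_props & doc$object_type == "literal", ]
  dplyr::bind_rows(
    consistency_errors_from("misused_datatype_property", "predicate", dt_rows),
    consistency_errors_from("misused_object_property", "predicate", ob_rows))
}

#' Find uses of deprecated classes or properties
#'
#' Every occurrence (any triple position) of a term whose definition graph
#' marks it deprecated is a use of a deprecated term. Deprecated terms are
#' still evaluated by the other consistency rules.
#'
#' @param doc Assessed document.
#' @param typings Tibble from [type_terms()].
#' @return Tibble of errors with witness triples.
#' @export
find_deprecated_uses <- function(doc, typings) {
  dep_cls <- typings$uri[typings$deprecated & typings$is_class]
  dep_prp <- typings$uri[typings$deprecated & typings$is_property &
                           !typings$is_class]
  use_rows <- function(uris) doc[triples_mentioning(doc, uris), ]
  cls_rows <- use_rows(dep_cls)
  prp_rows <- use_rows(dep_prp)
  witness_uri <- function(rows, uris) {
    vapply(seq_len(nrow(rows)), function(i) {
      cand <- c(rows$subject[i][rows$subject_type[i] == "uri"],
                rows$predicate[i],
                rows$object[i][rows$object_type[i] == "uri"])
      cand[cand %in% uris][1]
    }, character(1))
  }
  out <- list()
  if (nrow(cls_rows) > 0) {
    out$cls <- tibble::tibble(kind = "deprecated_class",
                              uri = witness_uri(cls_rows, dep_cls),
                              subject = cls_rows$subject,
                              predicate = cls_rows$predicate,
                              object = cls_rows$object,
                              witness = nt_lines(cls_rows))
  }
  if (nrow(prp_rows) > 0) {
    out$prp <- tibble::tibble(kind = "deprecated_property",
                              uri = witness_uri(prp_rows, dep_prp),
                              subject = prp_rows$subject,
                              predicate = prp_rows$predicate,
                              object = prp_rows$object,
                              witness = nt_lines(prp_rows))
  }
  dplyr::bind_rows(c(list(consistency_error_tibble()), out))
}

#' Run all consistency checks
#'
#' @param doc Assessed document.
#' @param typings Tibble from [type_terms()].
#' @param defining Defining-predicate exemption set for misplaced
#'   properties.
#' @return Tibble of all consistency errors (possibly zero rows). Named
#'   individuals that are neither classes nor properties never appear.
#' @export
find_consistency_errors <- function(doc, typings,
                                    defining = defining_predicates()) {
  typings <- typings[!(typings$is_named_individual &
                       !typings$is_class & !typings$is_property), ]
  dplyr::bind_rows(
    find_misplaced_classes(doc, typings),
    find_misplaced_properties(doc, typings, defining = defining),
    find_misused_property_flavors(doc, typings),
    find_deprecated_uses(doc, typings))
}
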