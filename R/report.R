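#' The six foundational quality metrics and their RDF identifiers
#'
#' The metric vocabulary lives at `http://purl.org/fqm#`. The published
#' vocabulary names the non-resolvable and undefined metrics; the remaining
#' four identifiers follow the same naming style and can be remapped via the
#' `metric_uris` argument of [build_report()] without code change.
#'
#' @return Tibble: `metric_id`, `uri`, `label`, `definition`.
#' @export
fqm_metrics <- function() {
  tibble::tibble(
    metric_id = METRIC_IDS,
    uri = unname(fqm_metric_uris()),
    label = c("Non-resolvable URIs", "Non-parsable URIs", "Undefined URIs",
              "Misplaced classes or properties",
              "Misuse of owl:DatatypeProperty or owl:ObjectProperty",
              "Use of deprecated classes or properties"),
    definition = c(
      "Proportion of unique non-resolvable URIs to all unique URIs; a URI is non-resolvable if dereferencing it ends in an HTTP error code such as 404.",
      "Proportion of unique non-parsable URIs to all unique URIs; a URI is non-parsable if its media type declares RDF content but the content cannot be parsed into at least one RDF triple.",
      "Proportion of unique undefined URIs to all unique URIs; a URI is undefined if it does not occur within the RDF triples obtained by resolving it.",
      "Proportion of classes used as a triple predicate, or properties used as a triple object outside defining triples, to all unique classes and properties.",
      "Proportion of owl:DatatypeProperty properties whose object is a URI, or owl:ObjectProperty properties whose object is a literal, to all unique properties.",
      "Proportion of deprecated classes or properties in use to all unique classes and properties."))
}

#' Default metric URI mapping
#' @return Named character vector, metric id -> metric URI.
#' @export
fqm_metric_uris <- function() {
  stats::setNames(paste0(FQM_NS, c(
    "uriNonResolvableMetric", "uriNonParsableMetric", "uriUndefinedMetric",
    "misplacedClassOrPropertyMetric", "misusedPropertyTypeMetric",
    "deprecatedClassOrPropertyMetric")), METRIC_IDS)
}

#' Metric descriptor graph
#'
#' Triples typing each metric as `dqv:Metric` with `skos:prefLabel` and
#' `skos:definition`, for loading alongside assessment reports so quality
#' questions can retrieve metric definitions.
#'
#' @param metric_uris Named mapping as [fqm_metric_uris()].
#' @return Triple tibble.
#' @export
fqm_graph <- function(metric_uris = fqm_metric_uris()) {
  m <- fqm_metrics()
  m$uri <- unname(metric_uris[m$metric_id])
  triples_from_list(c(
    purrr::map(seq_len(nrow(m)), function(i)
      list(m$uri[i], RDF_TYPE, paste0(DQV_NS, "Metric"))),
    purrr::map(seq_len(nrow(m)), function(i)
      list(m$uri[i], paste0(SKOS_NS, "prefLabel"), lit(m$label[i]))),
    purrr::map(seq_len(nrow(m)), function(i)
      list(m$uri[i], paste0(SKOS_NS, "definition"), lit(m$definition[i])))))
}

#' Mint the resource identifier for a report
#'
#' Absolute IRIs are used as-is; local file paths get a deterministic
#' `urn:rdfqa:resource:` identifier.
#'
#' @param locator Resource URI or file path.
#' @return Absolute IRI string.
#' @export
resource_identifier <- function(locator) {
  if (is_absolute_iri(locator)) return(locator)
  paste0("urn:rdfqa:resource:",
         gsub("[^A-Za-z0-9._-]", "_", basename(locator)))
}

measurement_uri <- function(resource_id, metric_id) {
  short <- c(non_resolvable_uris = "nonResolvable",
             non_parsable_uris = "nonParsable",
             undefined_uris = "undefined",
             misplaced_classes_or_properties = "misplaced",
             misused_datatype_or_object_property = "misusedPropertyType",
             deprecated_classes_or_properties = "deprecated")[[metric_id]]
  sep <- if (grepl("#", resource_id)) "-" else "#"
  paste0(resource_id, sep, "measurement-", short)
}

#' Build a DQV assessment report graph
#'
#' Produces the machine-readable assessment report: the resource is typed
#' `dcat:Resource` and linked to one `dqv:QualityMeasurement` node per
#' metric via `dqv:hasQualityMeasurement`. Each measurement carries the
#' metric (`dqv:isMeasurementOf`), the count pair as a `dqv:value` string
#' `"n/N"`, the generation time (`prov:generatedAtTime`, xsd:dateTime), and
#' one `dcterms:relation` link per erroneous URI. With
#' `failures_only = TRUE` only failed metrics (numerator > 0) get
#' measurement nodes, reproducing the published report layout; the default
#' keeps passed metrics as `"0/N"` measurements so "which metrics were
#' tested" remains queryable.
#'
#' @param resource_id Absolute IRI of the assessed resource (see
#'   [resource_identifier()]).
#' @param results Metric tibble from [compute_metric_results()].
#' @param generated_at `POSIXct` timestamp (defaults to now, UTC); fix it
#'   for reproducible reports.
#' @param failures_only Emit only failed metrics.
#' @param metric_uris Metric URI mapping (see [fqm_metric_uris()]).
#' @return Triple tibble of the report graph.
#' @export
build_report <- function(resource_id, results,
                         generated_at = Sys.time(),
                         failures_only = FALSE,
                         metric_uris = fqm_metric_uris()) {
  stamp <- format(as.POSIXct(generated_at, tz = "UTC"),
                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  parts <- list(rdf_triples(resource_id, RDF_TYPE, paste0(DCAT_NS, "Resource")))
  for (i in seq_len(nrow(results))) {
    if (failures_only && results$n_errors[i] == 0) next
    mid <- results$metric_id[i]
    mnode <- measurement_uri(resource_id, mid)
    parts <- c(parts, list(
      rdf_triples(
        subject = c(resource_id, mnode, mnode, mnode),
        predicate = c(paste0(DQV_NS, "hasQualityMeasurement"), RDF_TYPE,
                      paste0(DQV_NS, "computedOn"),
                      paste0(DQV_NS, "isMeasurementOf")),
        object = c(mnode, paste0(DQV_NS, "QualityMeasurement"), resource_id,
                   unname(metric_uris[mid]))),
      rdf_triples(
        subject = mnode,
        predicate = c(paste0(DQV_NS, "value"),
                      paste0(PROV_NS, "generatedAtTime")),
        object = c(results$value[i], stamp),
        object_type = "literal",
        object_datatype = c(NA_character_, XSD_DATETIME))))
    errs <- results$error_uris[[i]]
    if (length(errs) > 0) {
      parts <- c(parts, list(rdf_triples(
        subject = mnode, predicate = paste0(DCT_NS, "relation"),
        object = errs)))
    }
  }
  dplyr::distinct(dplyr::bind_rows(parts))
}

#' Write an assessment report as Turtle
#' @param report Report graph from [build_report()].
#' @param path Output `.ttl` path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  rdf_write(report, path, format = "turtle")
  invisible(path)
}
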