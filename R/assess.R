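#' Assess an RDF resource against the six foundational quality metrics
#'
#' Runs the full workflow: parse the document, extract the unique-URI
#' inventory, dereference every URI with RDF-preferring content negotiation,
#' cascade each URI to its verdict (non-resolvable / non-RDF content /
#' non-parsable / undefined / defined), type the defined terms from their
#' definition graphs, apply the consistency rules, and compute the six
#' metric results with affected-triple statistics.
#'
#' @param input A file path/URL, or a triple tibble already parsed.
#' @param transport Transport function; defaults to [live_transport()] when
#'   `offline_map` is `NULL`, otherwise [offline_transport()] over the map.
#' @param offline_map Fixture map (named list or JSON path) for offline
#'   assessment.
#' @param resource_id Identifier for the report; defaults to
#'   [resource_identifier()] of the input locator.
#' @param format,base Passed to [rdf_read()] when `input` is a locator.
#' @param retries,backoff,accept Passed to [resolve_uris()].
#' @param defining Defining-predicate exemption set
#'   ([defining_predicates()]).
#' @param property_types Property-typing URIs ([owl_property_types()] plus
#'   `rdf:Property`).
#' @param subject_only Use the stricter subject-only definition check.
#' @param generated_at Report timestamp (POSIXct); fix for reproducibility.
#' @return An object of class `rdfqa_assessment`: a list with `resource_id`,
#'   `doc`, `inventory`, `outcomes`, `verdicts`, `graphs`, `typings`,
#'   `consistency_errors`, `metrics`, `generated_at`. Use [generics::tidy()]
#'   for the per-metric table, [generics::glance()] for a one-row summary,
#'   [build_report()]/[report()] for the DQV graph.
#' @export
rdf_assess <- function(input, transport = NULL, offline_map = NULL,
                       resource_id = NULL, format = NULL, base = NULL,
                       retries = 3, backoff = 0,
                       accept = build_accept_header(),
                       defining = defining_predicates(),
                       property_types = c(RDF_PROPERTY, owl_property_types()),
                       subject_only = FALSE,
                       generated_at = Sys.time()) {
  if (is.data.frame(input)) {
    doc <- input
    if (is.null(resource_id)) resource_id <- "urn:rdfqa:resource:in-memory"
  } else {
    doc <- rdf_read(input, format = format, base = base)
    if (is.null(resource_id)) resource_id <- resource_identifier(input)
  }
  if (is.null(transport)) {
    transport <- if (is.null(offline_map)) live_transport()
                 else offline_transport(offline_map)
  } else if (!is.null(offline_map)) {
    rlang::abort("give either `transport` or `offline_map`, not both")
  }
  inventory <- rdf_inventory(doc)
  outcomes <- resolve_uris(inventory$unique_uris[[1]], transport,
                           accept = accept, retries = retries,
                           backoff = backoff)
  casc <- cascade_verdicts(outcomes, subject_only = subject_only)
  typings <- type_terms(casc$verdicts, casc$graphs,
                        property_types = property_types)
  cons <- find_consistency_errors(doc, typings, defining = defining)
  metrics <- compute_metric_results(doc, inventory, casc$verdicts, typings,
                                    cons)
  structure(list(
    resource_id = resource_id, doc = doc, inventory = inventory,
    outcomes = outcomes, verdicts = casc$verdicts, graphs = casc$graphs,
    typings = typings, consistency_errors = cons, metrics = metrics,
    generated_at = generated_at
  ), class = "rdfqa_assessment")
}

#' Build the DQV report graph of an assessment
#' @param x An `rdfqa_assessment`.
#' @param failures_only Emit only failed metrics (see [build_report()]).
#' @param metric_uris Metric URI mapping.
#' @return Triple tibble of the report graph.
#' @export
report <- function(x, failures_only = FALSE, metric_uris = fqm_metric_uris()) {
  stopifnot(inherits(x, "rdfqa_assessment"))
  build_report(x$resource_id, x$metrics, generated_at = x$generated_at,
               failures_only = failures_only, metric_uris = metric_uris)
}

#' @export
print.rdfqa_assessment <- function(x, ...) {
  inv <- x$inventory
  cat("RDF quality assessment of <", x$resource_id, ">\n", sep = "")
  cat(sprintf("  %d unique URIs, %d literals, %d blank nodes, %d triples\n",
              inv$n_uris, inv$n_literals, inv$n_blank_nodes, inv$n_triples))
  m <- x$metrics
  labels <- stats::setNames(fqm_metrics()$label, fqm_metrics()$metric_id)
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-52s %s   affected triples %s\n",
                labels[[m$metric_id[i]]], m$cell[i],
                format_cell(m$affected_triples[i], m$total_triples[i])))
  }
  invisible(x)
}

#' Tidy the per-metric results of an assessment
#'
#' @param x An `rdfqa_assessment`.
#' @param ... Unused.
#' @return The metric tibble of [compute_metric_results()].
#' @method tidy rdfqa_assessment
#' @export
tidy.rdfqa_assessment <- function(x, ...) x$metrics

#' One-row summary of an assessment
#'
#' @param x An `rdfqa_assessment`.
#' @param ... Unused.
#' @return Tibble with the inventory counts, the verdict-stage counts, and
#'   the total number of distinct error URIs across metrics.
#' @method glance rdfqa_assessment
#' @export
glance.rdfqa_assessment <- function(x, ...) {
  stages <- c("non_resolvable", "non_rdf_content", "non_parsable",
              "undefined", "defined")
  counts <- vapply(stages, function(s) sum(x$verdicts$stage == s), 0L)
  tibble::tibble(
    resource_id = x$resource_id,
    n_uris = x$inventory$n_uris,
    n_literals = x$inventory$n_literals,
    n_blank_nodes = x$inventory$n_blank_nodes,
    n_triples = x$inventory$n_triples,
    !!!as.list(counts),
    n_error_uris = length(unique(unlist(x$metrics$error_uris))),
    n_failed_metrics = sum(x$metrics$n_errors > 0))
}

#' Plot the error proportions of an assessment
#'
#' Bar chart of the six metrics: proportion of erroneous URIs (or terms)
#' and proportion of affected triples.
#'
#' @param object An `rdfqa_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rdfqa_assessment
#' @export
autoplot.rdfqa_assessment <- function(object, ...) {
  m <- object$metrics
  labels <- stats::setNames(fqm_metrics()$label, fqm_metrics()$metric_id)
  df <- dplyr::bind_rows(
    tibble::tibble(metric = unname(labels[m$metric_id]),
                   share = m$proportion, what = "error URIs / denominator"),
    tibble::tibble(metric = unname(labels[m$metric_id]),
                   share = m$affected_pct, what = "affected triples"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$share,
                                   fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion", fill = NULL,
                  title = "Foundational quality assessment") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
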