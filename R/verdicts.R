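#' Parse the retrieved content of a resolvable, RDF-typed response
#'
#' The parser is chosen from the normalized media type via the RDF
#' media-type table ([rdf_media_types()]); no format sniffing is performed
#' on mismatch — the metric is about the declared media type, so a Turtle
#' body served as `application/rdf+xml` is non-parsable, and prose served as
#' `text/plain` fails the strict N-Triples parser. Success requires at least
#' one triple: an empty-but-valid document does not contain an RDF graph and
#' is equally non-parsable.
#'
#' @param body Response body string.
#' @param content_type Normalized media type (an RDF one).
#' @param base Base IRI for relative IRIs (the request URL).
#' @return A triple tibble on success, or `NULL` when the content is
#'   non-parsable (a verdict, not an exception).
#' @export
parse_retrieved_content <- function(body, content_type, base = NULL) {
  fmt <- rdf_media_types()
  format <- fmt$format[match(content_type, fmt$media_type)]
  if (is.na(format)) return(NULL)
  g <- tryCatch(rdf_parse_string(body %||% "", format, base = base),
                rdfqa_parse_error = function(e) NULL,
                error = function(e) NULL)
  if (is.null(g) || nrow(g) == 0) return(NULL)
  g
}

#' Is a URI defined by its retrieved graph?
#'
#' A URI is defined iff the exact URI string occurs in any triple position
#' (subject, predicate, or object) of the graph obtained by resolving it.
#' Matching is purely syntactic: hash and hashless variants of the same
#' namespace are different URIs, so a document that only mentions
#' `...ns#` does not define `...ns`.
#'
#' @param uri URI string.
#' @param retrieved_graph Triple tibble parsed from the URI's response.
#' @param subject_only Restrict "defined" to occurrence in the subject
#'   position (a stricter comparison mode; default `FALSE`).
#' @return Logical scalar.
#' @export
check_defined <- function(uri, retrieved_graph, subject_only = FALSE) {
  if (subject_only) {
    return(any(retrieved_graph$subject == uri &
               retrieved_graph$subject_type == "uri"))
  }
  uri_occurs(uri, retrieved_graph)
}

#' Cascade every unique URI of a document to its terminal verdict
#'
#' Implements the assessment cascade: non-resolvable URIs (4xx/5xx, network
#' failure, or non-http scheme) stop first; resolvable URIs without an RDF
#' content-type stop as `non_rdf_content` and are not analyzed further (and
#' are not errors); RDF-typed content that yields no triples is
#' `non_parsable`; parsed content that does not mention the URI is
#' `undefined`; the rest are `defined`. Hash URIs sharing a document reuse
#' one fetched, parsed graph keyed by the defragmented request URI.
#'
#' @param outcomes Resolution tibble from [resolve_uris()].
#' @param subject_only Passed to [check_defined()].
#' @return A list with `verdicts`, a tibble (`uri`, `stage`, `status_code`,
#'   `content_type`, `detail`), and `graphs`, a named list of parsed
#'   definition graphs keyed by request URI.
#' @export
cascade_verdicts <- function(outcomes, subject_only = FALSE) {
  parsed <- new.env(parent = emptyenv())  # request_uri -> graph or NULL
  get_graph <- function(req, body, ct) {
    key <- paste0("g:", req)
    if (!is.null(parsed[[key]])) return(parsed[[key]]$g)
    g <- parse_retrieved_content(body, ct, base = req)
    parsed[[key]] <- list(g = g)
    g
  }
  rows <- purrr::pmap(outcomes, function(uri, request_uri, status_code,
                                         resolvable, content_type,
                                         is_rdf_content, final_url, reason,
                                         body, ...) {
    if (!resolvable) {
      detail <- switch(reason %||% "http_error",
        non_http_scheme = "URI scheme is not dereferenceable over HTTP",
        malformed_uri = "URI is not a valid absolute http(s) URI",
        network_error = "network failure after retries (sentinel status 0)",
        paste0("HTTP status ", status_code))
      return(tibble::tibble(uri = uri, stage = "non_resolvable",
                            status_code = status_code,
                            content_type = content_type, detail = detail))
    }
    if (!is_rdf_content) {
      return(tibble::tibble(uri = uri, stage = "non_rdf_content",
                            status_code = status_code,
                            content_type = content_type,
                            detail = paste0("content-type '",
                                            content_type %||% "absent",
                                            "' is not an RDF media type; not an error")))
    }
    g <- get_graph(request_uri, body, content_type)
    if (is.null(g)) {
      return(tibble::tibble(uri = uri, stage = "non_parsable",
                            status_code = status_code,
                            content_type = content_type,
                            detail = "RDF content-type but content yields no RDF triples"))
    }
    if (!check_defined(uri, g, subject_only = subject_only)) {
      return(tibble::tibble(uri = uri, stage = "undefined",
                            status_code = status_code,
                            content_type = content_type,
                            detail = "URI absent from the triples obtained by resolving it"))
    }
    tibble::tibble(uri = uri, stage = "defined", status_code = status_code,
                   content_type = content_type, detail = NA_character_)
  })
  graphs <- list()
  for (key in ls(parsed)) {
    g <- parsed[[key]]$g
    if (!is.null(g)) graphs[[substring(key, 3)]] <- g
  }
  list(verdicts = dplyr::bind_rows(rows), graphs = graphs)
}

#' Export verdicts as a CSV audit trail
#' @param verdicts Verdict tibble from [cascade_verdicts()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_verdicts_csv <- function(verdicts, path) {
  utils::write.csv(verdicts, path, row.names = FALSE, na = "")
  invisible(path)
}
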