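#' Build an RDF-preferring Accept header
#'
#' Lists every RDF media type with the highest factor weighting (an omitted
#' q-value means q=1) and `*/*` with the lowest, so servers return an RDF
#' serialization whenever one is available and anything else only as a last
#' resort.
#'
#' @param media_types Tibble as returned by [rdf_media_types()].
#' @return A single Accept header string.
#' @export
build_accept_header <- function(media_types = rdf_media_types()) {
  paste0(paste(unique(media_types$media_type), collapse = ", "),
         ", */*;q=0.1")
}

#' Offline transport from a fixture map
#'
#' Returns a transport function `f(uri, accept)` that replays canned HTTP
#' responses. The map is a named list (or path to a JSON file)
#' `uri -> list(status, content_type, body)`. Unknown URIs yield 404 unless
#' `strict = TRUE`, in which case they raise an error (guarding against
#' accidental live lookups). Every call is appended to an internal log,
#' retrievable with [transport_log()], so tests can count real fetches.
#'
#' @param map Named list or JSON file path.
#' @param strict Raise on URIs absent from the map instead of returning 404.
#' @return A transport function with attribute `log_env`.
#' @export
offline_transport <- function(map = list(), strict = FALSE) {
  if (is.character(map) && length(map) == 1) {
    map <- jsonlite::fromJSON(map, simplifyVector = FALSE)
  }
  log_env <- new.env(parent = emptyenv())
  log_env$uris <- character()
  f <- function(uri, accept = build_accept_header()) {
    log_env$uris <- c(log_env$uris, uri)
    entry <- map[[uri]]
    if (is.null(entry)) {
      if (strict) {
        rlang::abort(paste0("offline transport: no fixture for URI '", uri,
                            "'"), class = "rdfqa_transport_error")
      }
      return(list(status = 404L, content_type = NULL, body = "",
                  final_url = uri))
    }
    list(status = as.integer(entry$status %||% 200L),
         content_type = entry$content_type %||% NULL,
         body = entry$body %||% "",
         final_url = entry$final_url %||% uri)
  }
  attr(f, "log_env") <- log_env
  f
}

#' Fetch log of an offline transport
#' @param transport A transport built by [offline_transport()].
#' @return Character vector of request URIs in call order.
#' @export
transport_log <- function(transport) {
  env <- attr(transport, "log_env")
  if (is.null(env)) character() else env$uris
}

#' Live HTTP transport (via the curl command-line client)
#'
#' Follows redirects, applies the configured timeout, and returns the final
#' status code, media type, body, and effective URL. Live dereferencing is an
#' optional mode: all tests and the acceptance pipeline run on offline
#' fixture maps.
#'
#' @param timeout Seconds per attempt.
#' @param user_agent User-Agent request header.
#' @return A transport function `f(uri, accept)`.
#' @export
live_transport <- function(timeout = 30, user_agent = "rdfqa-quality-assessor/0.1") {
  function(uri, accept = build_accept_header()) {
    body_file <- tempfile()
    on.exit(unlink(body_file), add = TRUE)
    meta <- suppressWarnings(system2(
      "curl",
      c("-sS", "-L", "--max-time", as.character(timeout),
        "-A", shQuote(user_agent),
        "-H", shQuote(paste0("Accept: ", accept)),
        "-o", shQuote(body_file),
        "-w", shQuote("%{http_code}\t%{content_type}\t%{url_effective}"),
        shQuote(uri)),
      stdout = TRUE, stderr = FALSE))
    if (length(meta) == 0 || !grepl("^[0-9]{3}\t", meta[1])) {
      return(list(status = 0L, content_type = NULL, body = "",
                  final_url = uri))
    }
    parts <- strsplit(meta[1], "\t", fixed = TRUE)[[1]]
    body <- if (file.exists(body_file)) {
      paste(readLines(body_file, warn = FALSE), collapse = "\n")
    } else ""
    list(status = as.integer(parts[1]),
         content_type = if (is.na(parts[2]) || parts[2] == "") NULL else parts[2],
         body = body, final_url = parts[3] %||% uri)
  }
}

#' Create a resolution cache
#'
#' Memoizes HTTP outcomes per defragmented request-URI so repeated
#' classification runs over the same transport make zero new fetches.
#' @return An environment usable as the `cache` argument of [resolve_uris()].
#' @export
resolution_cache <- function() new.env(parent = emptyenv())

normalize_content_type <- function(ct) {
  if (is.null(ct) || length(ct) == 0 || is.na(ct[1]) || ct[1] == "") {
    return(NA_character_)
  }
  tolower(trimws(sub(";.*$", "", ct[1])))
}

strip_fragment <- function(uri) sub("#.*$", "", uri)

is_http_uri <- function(uri) grepl("^https?://[^ ]+$", uri) & !grepl("\\s", uri)

#' Resolve a set of URIs and classify resolvability
#'
#' Dereferences each unique URI with RDF-preferring content negotiation and
#' classifies the outcome. The fragment is stripped for the HTTP request
#' (standard dereferencing), but verdicts are recorded against the full URI
#' string, so hash URIs sharing a document produce a single fetch and one
#' outcome row each. Status codes 4xx/5xx mean non-resolvable; network
#' failures map to the sentinel status 0; non-`http(s)` schemes and
#' malformed URIs are non-resolvable with a distinct reason and are never
#' fetched. Responses with 5xx or 429 status are retried with exponential
#' backoff.
#'
#' @param uris Character vector of URIs (typically
#'   `rdf_inventory(g)$unique_uris[[1]]`).
#' @param transport Transport function (see [offline_transport()],
#'   [live_transport()]).
#' @param accept Accept header string.
#' @param retries Additional attempts for retryable failures (5xx, 429,
#'   transport errors).
#' @param backoff Base seconds for exponential backoff between retries
#'   (`backoff * 2^(attempt-1)`); use 0 in offline runs.
#' @param cache A [resolution_cache()]; pass the same cache across calls to
#'   guarantee each distinct request-URI is fetched at most once overall.
#' @return Tibble with one row per input URI: `uri`, `request_uri`,
#'   `status_code`, `resolvable`, `content_type`, `is_rdf_content`,
#'   `final_url`, `reason`, and a `body` list-column.
#' @export
resolve_uris <- function(uris, transport, accept = build_accept_header(),
                         retries = 3, backoff = 0, cache = resolution_cache()) {
  uris <- unique(uris)
  rdf_types <- rdf_media_types()$media_type
  fetch_cached <- function(req) {
    key <- paste0("u:", req)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- NULL
    for (attempt in seq_len(retries + 1)) {
      res <- tryCatch(transport(req, accept),
                      error = function(e) list(status = 0L, content_type = NULL,
                                               body = "", final_url = req))
      if (!res$status %in% c(0L, 429L) && res$status < 500L) break
      if (attempt <= retries && backoff > 0) Sys.sleep(backoff * 2^(attempt - 1))
    }
    cache[[key]] <- res
    res
  }
  rows <- purrr::map(uris, function(u) {
    if (!is_http_uri(u)) {
      reason <- if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", u)) "non_http_scheme"
                else "malformed_uri"
      return(tibble::tibble(
        uri = u, request_uri = NA_character_, status_code = 0L,
        resolvable = FALSE, content_type = NA_character_,
        is_rdf_content = FALSE, final_url = NA_character_,
        reason = reason, body = list(NULL)))
    }
    req <- strip_fragment(u)
    res <- fetch_cached(req)
    ct <- normalize_content_type(res$content_type)
    resolvable <- res$status >= 100L && res$status < 400L
    tibble::tibble(
      uri = u, request_uri = req, status_code = as.integer(res$status),
      resolvable = resolvable, content_type = ct,
      is_rdf_content = resolvable && !is.na(ct) && ct %in% rdf_types,
      final_url = res$final_url %||% req,
      reason = if (resolvable) NA_character_
               else if (res$status == 0L) "network_error" else "http_error",
      body = list(if (resolvable) res$body else NULL))
  })
  dplyr::bind_rows(rows)
}
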