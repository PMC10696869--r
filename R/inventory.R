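#' Extract the component inventory of an RDF document
#'
#' The assessment workflow operates on the components of a parsed document:
#' the set of unique URIs (deduplicated by exact string comparison, so URIs
#' differing only by a `#fragment` are distinct entries), the number of
#' literal occurrences (one per triple object slot, not deduplicated), the
#' number of distinct blank nodes, and the triple count.
#'
#' @param g Triple tibble (see [rdf_triples()]).
#' @return One-row tibble with columns `n_uris`, `n_literals`,
#'   `n_blank_nodes`, `n_triples`, and a list-column `unique_uris` holding
#'   the sorted URI set.
#' @export
rdf_inventory <- function(g) {
  uris <- rdf_unique_uris(g)
  blanks <- unique(c(g$subject[g$subject_type == "blank"],
                     g$object[g$object_type == "blank"]))
  tibble::tibble(
    n_uris = length(uris),
    n_literals = sum(g$object_type == "literal"),
    n_blank_nodes = length(blanks),
    n_triples = nrow(g),
    unique_uris = list(uris)
  )
}

#' Unique URIs of a document, in sorted order
#'
#' Collects every URI occurring in any triple position (subject, predicate,
#' or object), deduplicated by exact string equality.
#'
#' @param g Triple tibble.
#' @return Character vector of absolute URIs.
#' @export
rdf_unique_uris <- function(g) {
  sort(unique(c(g$subject[g$subject_type == "uri"],
                g$predicate,
                g$object[g$object_type == "uri"])))
}

# does `uri` occur in any position of graph g? (exact string matching)
uri_occurs <- function(uri, g) {
  any(g$predicate == uri) ||
    any(g$subject == uri & g$subject_type == "uri") ||
    any(g$object == uri & g$object_type == "uri")
}

# rows of g that mention at least one URI of `uris` in any position
triples_mentioning <- function(g, uris) {
  if (length(uris) == 0 || nrow(g) == 0) return(rep(FALSE, nrow(g)))
  (g$subject_type == "uri" & g$subject %in% uris) |
    g$predicate %in% uris |
    (g$object_type == "uri" & g$object %in% uris)
}
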