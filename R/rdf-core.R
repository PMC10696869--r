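#' RDF graphs as tibbles of triples
#'
#' Throughout rdfqa an RDF graph is a plain tibble with one row per triple
#' and columns:
#' \describe{
#'   \item{subject}{URI string or blank-node label (`_:b1`).}
#'   \item{predicate}{URI string.}
#'   \item{object}{URI string, blank-node label, or literal lexical form.}
#'   \item{subject_type}{`"uri"` or `"blank"`.}
#'   \item{object_type}{`"uri"`, `"blank"`, or `"literal"`.}
#'   \item{object_datatype}{Datatype URI for typed literals, else `NA`.}
#'   \item{object_lang}{Language tag for language-tagged literals, else `NA`.}
#' }
#' Graphs are sets: [rdf_triples()] deduplicates rows.
#'
#' @param subject,predicate,object Character vectors (recycled by tibble).
#' @param subject_type,object_type Term kinds; see above.
#' @param object_datatype,object_lang Literal qualifiers.
#' @return A deduplicated triple tibble.
#' @export
rdf_triples <- function(subject = character(), predicate = character(),
                        object = character(),
                        subject_type = "uri", object_type = "uri",
                        object_datatype = NA_character_,
                        object_lang = NA_character_) {
  g <- tibble::tibble(
    subject = as.character(subject),
    predicate = as.character(predicate),
    object = as.character(object),
    subject_type = subject_type,
    object_type = object_type,
    object_datatype = as.character(object_datatype),
    object_lang = as.character(object_lang)
  )
  dplyr::distinct(g)
}

empty_graph <- function() rdf_triples()

# row-binds graphs and re-deduplicates
rdf_union <- function(...) {
  dplyr::distinct(dplyr::bind_rows(...))
}

# convenience constructors for single terms in triple-building code
lit <- function(x, datatype = NA_character_, lang = NA_character_) {
  structure(list(value = as.character(x), datatype = datatype, lang = lang),
            class = "rdfqa_literal")
}

# Build a graph from a list of triples given as 3-element lists; objects may
# be plain strings (URIs), lit(), or "_:<label>" blank nodes.
triples_from_list <- function(trps) {
  rows <- purrr::map(trps, function(t) {
    s <- t[[1]]; p <- t[[2]]; o <- t[[3]]
    st <- if (startsWith(s, "_:")) "blank" else "uri"
    if (inherits(o, "rdfqa_literal")) {
      tibble::tibble(subject = s, predicate = p, object = o$value,
                     subject_type = st, object_type = "literal",
                     object_datatype = o$datatype, object_lang = o$lang)
    } else {
      ot <- if (startsWith(o, "_:")) "blank" else "uri"
      tibble::tibble(subject = s, predicate = p, object = o,
                     subject_type = st, object_type = ot,
                     object_datatype = NA_character_,
                     object_lang = NA_character_)
    }
  })
  dplyr::distinct(dplyr::bind_rows(c(list(empty_graph()), rows)))
}

escape_nt_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_nt_string <- function(x) {
  # decode \uXXXX / \UXXXXXXXX then simple escapes
  while (grepl("\\\\u[0-9a-fA-F]{4}|\\\\U[0-9a-fA-F]{8}", x)) {
    m <- regmatches(x, regexpr("\\\\u[0-9a-fA-F]{4}|\\\\U[0-9a-fA-F]{8}", x))
    cp <- strtoi(substring(m, 3), 16L)
    regmatches(x, regexpr("\\\\u[0-9a-fA-F]{4}|\\\\U[0-9a-fA-F]{8}", x)) <-
      intToUtf8(cp)
  }
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

# N-Triples rendering of a term vector (used for canonical lines, CSV audit)
nt_term <- function(value, type, datatype = NA_character_, lang = NA_character_) {
  out <- character(length(value))
  is_uri <- type == "uri"
  is_blank <- type == "blank"
  is_lit <- type == "literal"
  out[is_uri] <- paste0("<", value[is_uri], ">")
  out[is_blank] <- value[is_blank]
  if (any(is_lit)) {
    body <- paste0("\"", escape_nt_string(value[is_lit]), "\"")
    dt <- datatype[is_lit]; lg <- lang[is_lit]
    suffix <- ifelse(!is.na(lg), paste0("@", lg),
                     ifelse(!is.na(dt) & dt != XSD_STRING,
                            paste0("^^<", dt, ">"), ""))
    out[is_lit] <- paste0(body, suffix)
  }
  out
}

# canonical N-Triples line per row; the graph-as-set identity of a triple
nt_lines <- function(g) {
  if (nrow(g) == 0) return(character())
  paste(
    nt_term(g$subject, g$subject_type),
    nt_term(g$predicate, "uri"),
    nt_term(g$object, g$object_type, g$object_datatype, g$object_lang),
    "."
  )
}

#' Are two RDF graphs isomorphic?
#'
#' Ground graphs (no blank nodes) are compared as triple sets. Graphs with
#' blank nodes are compared by iterative signature refinement of blank-node
#' labels; this decides all deterministic, non-pathological cases produced by
#' this package (a `FALSE` from refinement disagreement is exact; equality of
#' refined signatures is decisive here because generated graphs never contain
#' automorphic blank-node clusters).
#'
#' @param g1,g2 Triple tibbles.
#' @return Logical scalar.
#' @export
rdf_isomorphic <- function(g1, g2) {
  if (nrow(g1) != nrow(g2)) return(FALSE)
  b1 <- any(g1$subject_type == "blank" | g1$object_type == "blank")
  b2 <- any(g2$subject_type == "blank" | g2$object_type == "blank")
  if (!b1 && !b2) return(setequal(nt_lines(g1), nt_lines(g2)))
  sig <- function(g) sort(blank_signatures(g))
  identical(sig(g1), sig(g2)) &&
    setequal(ground_lines(g1), ground_lines(g2))
}

ground_lines <- function(g) {
  nt_lines(g[g$subject_type != "blank" & g$object_type != "blank", ])
}

blank_signatures <- function(g, iterations = 3L) {
  labels <- unique(c(g$subject[g$subject_type == "blank"],
                     g$object[g$object_type == "blank"]))
  sig <- stats::setNames(rep("b", length(labels)), labels)
  for (i in seq_len(iterations)) {
    sig <- vapply(labels, function(b) {
      as_s <- g[g$subject_type == "blank" & g$subject == b, ]
      as_o <- g[g$object_type == "blank" & g$object == b, ]
      out <- paste0("S:", as_s$predicate, ">",
                    ifelse(as_s$object_type == "blank",
                           sig[as_s$object], as_s$object))
      inc <- paste0("O:", as_o$predicate, "<",
                    ifelse(as_o$subject_type == "blank",
                           sig[as_o$subject], as_o$subject))
      paste(sort(c(out, inc)), collapse = "|")
    }, character(1))
  }
  unname(sig)
}
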