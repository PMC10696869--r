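#' Serialize a triple tibble
#'
#' `rdf_serialize()` renders a graph as Turtle or N-Triples text;
#' `rdf_write()` writes it to a file. Turtle output groups triples by subject
#' with `;` predicate lists and abbreviates URIs using the supplied prefix
#' table. Output is deterministic: subjects, predicates, and objects are
#' emitted in the row order of the (deduplicated) input tibble.
#'
#' @param g Triple tibble (see [rdf_triples()]).
#' @param format `"turtle"` or `"ntriples"`.
#' @param prefixes Named character vector, prefix -> namespace URI, used for
#'   Turtle abbreviation. Defaults to the vocabularies the package emits.
#' @return A single string (`rdf_serialize`) or, invisibly, the path
#'   (`rdf_write`).
#' @export
rdf_serialize <- function(g, format = c("turtle", "ntriples"),
                          prefixes = default_prefixes()) {
  format <- match.arg(format)
  if (format == "ntriples") {
    return(paste0(paste(nt_lines(g), collapse = "\n"),
                  if (nrow(g)) "\n" else ""))
  }
  serialize_turtle(g, prefixes)
}

#' @rdname rdf_serialize
#' @param path Output file path.
#' @export
rdf_write <- function(g, path, format = c("turtle", "ntriples"),
                      prefixes = default_prefixes()) {
  writeLines(rdf_serialize(g, format, prefixes), path, useBytes = TRUE)
  invisible(path)
}

#' Default prefix table used when writing Turtle
#' @return Named character vector (prefix -> namespace URI).
#' @export
default_prefixes <- function() {
  c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS,
    dqv = DQV_NS, dcat = DCAT_NS, dcterms = DCT_NS, prov = PROV_NS,
    skos = SKOS_NS, fqm = FQM_NS)
}

abbrev_uri <- function(uri, prefixes) {
  for (p in names(prefixes)) {
    ns <- prefixes[[p]]
    if (startsWith(uri, ns)) {
      local <- substring(uri, nchar(ns) + 1L)
      # only abbreviate locals that are safe PN_LOCAL tokens
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_-]*$", local)) {
        return(paste0(p, ":", local))
      }
    }
  }
  paste0("<", uri, ">")
}

turtle_term <- function(value, type, datatype, lang, prefixes) {
  if (type == "uri") return(abbrev_uri(value, prefixes))
  if (type == "blank") return(value)
  body <- paste0("\"", escape_nt_string(value), "\"")
  if (!is.na(lang)) return(paste0(body, "@", lang))
  if (!is.na(datatype) && datatype != XSD_STRING) {
    return(paste0(body, "^^", abbrev_uri(datatype, prefixes)))
  }
  body
}

serialize_turtle <- function(g, prefixes) {
  used_ns <- vapply(names(prefixes), function(p) {
    ns <- prefixes[[p]]
    any(startsWith(g$subject, ns)) || any(startsWith(g$predicate, ns)) ||
      any(startsWith(g$object[g$object_type == "uri"], ns)) ||
      any(startsWith(stats::na.omit(g$object_datatype), ns))
  }, logical(1))
  header <- if (any(used_ns)) {
    paste0("@prefix ", names(prefixes)[used_ns], ": <",
           unname(prefixes[used_ns]), "> .")
  } else character(0)
  if (nrow(g) == 0) return(paste0(paste(header, collapse = "\n"), "\n"))

  subj_key <- paste(g$subject_type, g$subject)
  blocks <- character()
  for (sk in unique(subj_key)) {
    rows <- g[subj_key == sk, ]
    sterm <- if (rows$subject_type[1] == "blank") rows$subject[1]
             else abbrev_uri(rows$subject[1], prefixes)
    plines <- character()
    for (p in unique(rows$predicate)) {
      prow <- rows[rows$predicate == p, ]
      pterm <- if (p == RDF_TYPE) "a" else abbrev_uri(p, prefixes)
      objs <- vapply(seq_len(nrow(prow)), function(i) {
        turtle_term(prow$object[i], prow$object_type[i],
                    prow$object_datatype[i], prow$object_lang[i], prefixes)
      }, character(1))
      plines <- c(plines, paste0(pterm, " ", paste(objs, collapse = ", ")))
    }
    blocks <- c(blocks, paste0(sterm, " ",
                               paste(plines, collapse = " ;\n    "), " ."))
  }
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(blocks, collapse = "\n\n"), "\n")
}
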