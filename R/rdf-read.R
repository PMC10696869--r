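#' Read an RDF document into a triple tibble
#'
#' Parses Turtle, N-Triples, RDF/XML, JSON-LD, or Notation 3 from a local
#' file or an `http(s)://` URL. The serialization is taken from `format` if
#' given, otherwise detected from the file extension and finally by content
#' sniffing. Parse failures raise a condition of class `rdfqa_parse_error`
#' whose message names the serialization that was tried.
#'
#' @param path_or_url File path or URL.
#' @param format One of `"turtle"`, `"ntriples"`, `"rdfxml"`, `"jsonld"`,
#'   `"n3"`, or `NULL` to auto-detect. An explicit format always wins.
#' @param base Base IRI for resolving relative IRIs; defaults to the
#'   document's own locator. Relative IRIs without any usable base are an
#'   error.
#' @return A triple tibble (see [rdf_triples()]).
#' @export
rdf_read <- function(path_or_url, format = NULL, base = NULL) {
  if (!is.null(format)) format <- match_format(format)
  is_url <- grepl("^https?://", path_or_url)
  if (!is_url && !file.exists(path_or_url)) {
    rlang::abort(paste0("cannot read RDF document: '", path_or_url,
                        "' does not exist"), class = "rdfqa_io_error")
  }
  text <- paste(readLines(path_or_url, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  if (is.null(base)) {
    base <- if (is_url) path_or_url
            else paste0("file://", normalizePath(path_or_url, winslash = "/"))
  }
  if (is.null(format)) {
    format <- detect_format(path_or_url, text)
  }
  rdf_parse_string(text, format, base = base)
}

match_format <- function(format) {
  fmt <- tolower(format)
  ok <- c("turtle", "ntriples", "rdfxml", "jsonld", "n3",
          "ttl", "nt", "xml", "json-ld")
  if (!fmt %in% ok) {
    rlang::abort(paste0("unknown RDF serialization hint: '", format, "'"),
                 class = "rdfqa_format_error")
  }
  switch(fmt, ttl = "turtle", nt = "ntriples", xml = "rdfxml",
         `json-ld` = "jsonld", fmt)
}

detect_format <- function(locator, text) {
  ext <- tolower(sub(".*\\.", "", sub("[?#].*$", "", locator)))
  by_ext <- c(ttl = "turtle", turtle = "turtle", nt = "ntriples",
              rdf = "rdfxml", owl = "rdfxml", xml = "rdfxml",
              jsonld = "jsonld", json = "jsonld", n3 = "n3")
  if (ext %in% names(by_ext)) return(unname(by_ext[ext]))
  sniff_format(text)
}

sniff_format <- function(text) {
  head <- sub("^[\\s﻿]*", "", substr(text, 1, 2000), perl = TRUE)
  if (grepl("^<\\?xml|^<rdf:RDF|^<RDF", head)) return("rdfxml")
  if (grepl("^[{\\[]", head)) return("jsonld")
  nt_like <- grepl("^(<[^>]*>|_:\\S+)\\s+<[^>]*>\\s+\\S.*\\.\\s*$",
                   strsplit(head, "\n")[[1]][1] %||% "")
  if (grepl("@prefix|@base|PREFIX\\s|BASE\\s", head)) return("turtle")
  if (nt_like) return("ntriples")
  "turtle"
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Parse an RDF document from a string
#'
#' @param text Document content.
#' @param format Serialization name (see [rdf_read()]); required.
#' @param base Base IRI for relative IRI resolution.
#' @return A triple tibble.
#' @export
rdf_parse_string <- function(text, format, base = NULL) {
  format <- match_format(format)
  parser <- switch(format,
    turtle = parse_turtle, n3 = parse_turtle,
    ntriples = parse_ntriples,
    rdfxml = parse_rdfxml, jsonld = parse_jsonld)
  tryCatch(parser(text, base = base),
    rdfqa_parse_error = function(e) rlang::abort(conditionMessage(e),
                                                 class = "rdfqa_parse_error"),
    error = function(e) {
      rlang::abort(paste0("cannot parse content as ", format, ": ",
                          conditionMessage(e)),
                   class = "rdfqa_parse_error")
    })
}

parse_fail <- function(format, why) {
  rlang::abort(paste0("cannot parse content as ", format, ": ", why),
               class = "rdfqa_parse_error")
}

# ---- IRI resolution (RFC 3986 subset sufficient for RDF bases) ----

is_absolute_iri <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)

resolve_iri <- function(ref, base) {
  if (is_absolute_iri(ref)) return(ref)
  if (is.null(base)) {
    rlang::abort(paste0("relative IRI '", ref,
                        "' with no document base to resolve against"),
                 class = "rdfqa_parse_error")
  }
  if (ref == "") return(sub("#.*$", "", base))
  if (startsWith(ref, "#")) return(paste0(sub("#.*$", "", base), ref))
  m <- regmatches(base, regexec("^([A-Za-z][A-Za-z0-9+.-]*:)(//[^/?#]*)?([^?#]*)", base))[[1]]
  scheme <- m[2]; authority <- m[3]; path <- m[4]
  if (startsWith(ref, "//")) return(paste0(scheme, ref))
  if (startsWith(ref, "?")) return(paste0(scheme, authority, path, ref))
  if (startsWith(ref, "/")) {
    new_path <- ref
  } else {
    dir <- sub("[^/]*$", "", path)
    new_path <- paste0(dir, ref)
  }
  # dot-segment removal
  segs <- strsplit(new_path, "/", fixed = TRUE)[[1]]
  out <- character()
  for (s in segs) {
    if (s == ".") next
    if (s == "..") { if (length(out) > 1) out <- out[-length(out)] }
    else out <- c(out, s)
  }
  if (grepl("/(\\.\\.?)?$", new_path)) out <- c(out, "")
  paste0(scheme, authority, paste(out, collapse = "/"))
}

# ---- Turtle (and Notation 3 subset) ----

TURTLE_TOKEN_RE <- paste0(
  "(?s)",
  '"""(?:[^"\\\\]|\\\\.|"(?!""))*"""',     "|",
  "'''(?:[^'\\\\]|\\\\.|'(?!''))*'''",     "|",
  '"(?:[^"\\\\\\n]|\\\\.)*"',              "|",
  "'(?:[^'\\\\\\n]|\\\\.)*'",              "|",
  "<[^<>\"{}|^`\\\\\\x00-\\x20]*>",        "|",
  "#[^\\n]*",                               "|",
  "\\^\\^",                                 "|",
  "@[A-Za-z][A-Za-z0-9-]*",                 "|",
  "_:[A-Za-z0-9_][A-Za-z0-9_.-]*",          "|",
  "(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_:%.-]*", "|",
  "[+-]?(?:[0-9]+\\.[0-9]+|\\.[0-9]+|[0-9]+)(?:[eE][+-]?[0-9]+)?", "|",
  "[A-Za-z][A-Za-z0-9_]*",                  "|",
  "[][();,.]"
)

tokenize_turtle <- function(text) {
  m <- gregexpr(TURTLE_TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  toks <- regmatches(text, list(m))[[1]]
  toks <- toks[!startsWith(toks, "#")]
  # PN_LOCAL and blank-node labels must not end with '.': split trailing dots
  # off into their own statement-terminator tokens
  needs_fix <- function(t) grepl("^(_:|[A-Za-z_]|[A-Za-z_.-]*:)", t) &
    grepl("\\.$", t) & t != "."
  while (any(fix <- needs_fix(toks))) {
    out <- as.list(toks)
    for (i in which(fix)) out[[i]] <- c(sub("\\.$", "", toks[i]), ".")
    toks <- unlist(out)
  }
  toks[nzchar(toks)]
}

parse_turtle <- function(text, base = NULL) {
  toks <- tokenize_turtle(text)
  # verify tokenization consumed everything meaningful: strip tokens and
  # comments from the text; only whitespace may remain
  residue <- text
  residue <- gsub(TURTLE_TOKEN_RE, " ", residue, perl = TRUE)
  if (grepl("[^\\s﻿]", residue, perl = TRUE)) {
    parse_fail("turtle", paste0("unexpected characters: '",
      trimws(substr(gsub("[\\s﻿]+", " ", residue, perl = TRUE), 1, 40)),
      "'"))
  }

  st <- new.env(parent = emptyenv())
  st$i <- 1L; st$toks <- toks; st$n <- length(toks)
  st$prefixes <- list(); st$base <- base
  st$bn <- 0L
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 256L); acc$k <- 0L

  emit <- function(s, stype, p, o, otype, dt = NA_character_, lg = NA_character_) {
    acc$k <- acc$k + 1L
    if (acc$k > length(acc$rows)) length(acc$rows) <- 2L * length(acc$rows)
    acc$rows[[acc$k]] <- list(s, p, o, stype, otype, dt, lg)
  }
  peek <- function() if (st$i <= st$n) st$toks[st$i] else NA_character_
  advance <- function() { t <- peek(); st$i <- st$i + 1L; t }
  expect <- function(tok) {
    t <- advance()
    if (is.na(t) || t != tok) parse_fail("turtle",
      paste0("expected '", tok, "' but found '", t %||% "<end>", "'"))
    t
  }
  fresh_bnode <- function() { st$bn <- st$bn + 1L; paste0("_:genid", st$bn) }

  expand_pname <- function(tok) {
    cpos <- regexpr(":", tok, fixed = TRUE)
    prefix <- substr(tok, 1, cpos - 1L)
    local <- substring(tok, cpos + 1L)
    ns <- st$prefixes[[paste0(prefix, ":")]]  # keys stored with the colon
    if (is.null(ns)) parse_fail("turtle", paste0("undeclared prefix '",
                                                 prefix, ":'"))
    local <- gsub("\\\\([~.!$&'()*+,;=/?#@%_-])", "\\1", local)
    paste0(ns, local)
  }

  parse_iri_tok <- function(tok) {
    if (startsWith(tok, "<")) {
      resolve_iri(unescape_nt_string(substr(tok, 2, nchar(tok) - 1L)), st$base)
    } else expand_pname(tok)
  }

  read_string_tok <- function(tok) {
    if (startsWith(tok, '"""') || startsWith(tok, "'''")) {
      unescape_nt_string(substr(tok, 4, nchar(tok) - 3L))
    } else {
      unescape_nt_string(substr(tok, 2, nchar(tok) - 1L))
    }
  }

  # returns list(value, type, dt, lg)
  parse_object <- function() {
    t <- peek()
    if (is.na(t)) parse_fail("turtle", "unexpected end of input in object")
    if (t == "[") return(list(parse_bnode_property_list(), "blank",
                              NA_character_, NA_character_))
    if (t == "(") parse_fail("turtle", "RDF collections '( ... )' are not supported")
    advance()
    if (startsWith(t, "_:")) return(list(t, "blank", NA_character_, NA_character_))
    if (grepl('^["\']', t)) {
      val <- read_string_tok(t)
      nxt <- peek()
      if (!is.na(nxt) && nxt == "^^") {
        advance(); dt <- parse_iri_tok(advance())
        return(list(val, "literal", dt, NA_character_))
      }
      if (!is.na(nxt) && grepl("^@[A-Za-z]", nxt) &&
          !nxt %in% c("@prefix", "@base")) {
        advance()
        return(list(val, "literal", NA_character_, substring(nxt, 2)))
      }
      return(list(val, "literal", NA_character_, NA_character_))
    }
    if (t %in% c("true", "false"))
      return(list(t, "literal", XSD_BOOLEAN, NA_character_))
    if (grepl("^[+-]?[.0-9]", t)) {
      dt <- if (grepl("[eE]", t)) paste0(XSD_NS, "double")
            else if (grepl("\\.", t)) paste0(XSD_NS, "decimal")
            else paste0(XSD_NS, "integer")
      return(list(t, "literal", dt, NA_character_))
    }
    if (startsWith(t, "<") || grepl(":", t, fixed = TRUE))
      return(list(parse_iri_tok(t), "uri", NA_character_, NA_character_))
    parse_fail("turtle", paste0("unexpected token '", t, "' in object position"))
  }

  parse_verb <- function() {
    t <- advance()
    if (is.na(t)) parse_fail("turtle", "unexpected end of input in predicate")
    if (t == "a") return(RDF_TYPE)
    if (startsWith(t, "<") || grepl(":", t, fixed = TRUE))
      return(parse_iri_tok(t))
    parse_fail("turtle", paste0("unexpected token '", t, "' in predicate position"))
  }

  parse_predicate_object_list <- function(s, stype) {
    repeat {
      p <- parse_verb()
      repeat {
        o <- parse_object()
        emit(s, stype, p, o[[1]], o[[2]], o[[3]], o[[4]])
        if (!is.na(peek()) && peek() == ",") { advance(); next }
        break
      }
      if (!is.na(peek()) && peek() == ";") {
        advance()
        while (!is.na(peek()) && peek() == ";") advance()
        if (!is.na(peek()) && (peek() %in% c(".", "]"))) break
        next
      }
      break
    }
  }

  parse_bnode_property_list <- function() {
    expect("[")
    b <- fresh_bnode()
    if (!is.na(peek()) && peek() != "]") parse_predicate_object_list(b, "blank")
    expect("]")
    b
  }

  while (st$i <= st$n) {
    t <- peek()
    if (t %in% c("@prefix", "PREFIX")) {
      advance()
      pn <- advance()
      if (is.na(pn) || !grepl(":$", pn)) parse_fail("turtle",
        "expected 'prefix:' in @prefix directive")
      iri_tok <- advance()
      if (is.na(iri_tok) || !startsWith(iri_tok, "<"))
        parse_fail("turtle", "expected IRI in @prefix directive")
      iri <- substr(iri_tok, 2, nchar(iri_tok) - 1L)
      if (!is_absolute_iri(iri)) iri <- resolve_iri(iri, st$base)
      st$prefixes[[pn]] <- iri
      if (t == "@prefix") expect(".")
      next
    }
    if (t %in% c("@base", "BASE")) {
      advance()
      iri_tok <- advance()
      if (is.na(iri_tok) || !startsWith(iri_tok, "<"))
        parse_fail("turtle", "expected IRI in @base directive")
      st$base <- resolve_iri(substr(iri_tok, 2, nchar(iri_tok) - 1L), st$base)
      if (t == "@base") expect(".")
      next
    }
    # triples
    if (t == "[") {
      b <- parse_bnode_property_list()
      if (!is.na(peek()) && peek() != ".") parse_predicate_object_list(b, "blank")
      expect(".")
      next
    }
    if (t == "(") parse_fail("turtle", "RDF collections '( ... )' are not supported")
    subj_tok <- advance()
    if (startsWith(subj_tok, "_:")) {
      parse_predicate_object_list(subj_tok, "blank")
    } else if (startsWith(subj_tok, "<") || grepl(":", subj_tok, fixed = TRUE)) {
      parse_predicate_object_list(parse_iri_tok(subj_tok), "uri")
    } else {
      parse_fail("turtle", paste0("unexpected token '", subj_tok,
                                  "' in subject position"))
    }
    expect(".")
  }

  rows <- acc$rows[seq_len(acc$k)]
  if (length(rows) == 0) return(empty_graph())
  rdf_triples(
    subject = vapply(rows, `[[`, "", 1L),
    predicate = vapply(rows, `[[`, "", 2L),
    object = vapply(rows, `[[`, "", 3L),
    subject_type = vapply(rows, `[[`, "", 4L),
    object_type = vapply(rows, `[[`, "", 5L),
    object_datatype = vapply(rows, `[[`, "", 6L),
    object_lang = vapply(rows, `[[`, "", 7L)
  )
}

# ---- N-Triples (strict, line-based) ----

NT_LINE_RE <- paste0(
  "^\\s*",
  "(<[^>]*>|_:[A-Za-z0-9_][A-Za-z0-9_.-]*)\\s+",
  "(<[^>]*>)\\s+",
  '(<[^>]*>|_:[A-Za-z0-9_][A-Za-z0-9_.-]*|"(?:[^"\\\\]|\\\\.)*"',
  '(?:\\^\\^<[^>]*>|@[A-Za-z][A-Za-z0-9-]*)?)',
  "\\s*\\.\\s*$"
)

parse_ntriples <- function(text, base = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(empty_graph())
  m <- regmatches(lines, regexec(NT_LINE_RE, lines, perl = TRUE))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    parse_fail("ntriples", paste0("invalid N-Triples line: '",
                                  trimws(substr(lines[bad][1], 1, 60)), "'"))
  }
  term <- function(x) {
    if (startsWith(x, "<")) {
      list(v = substr(x, 2, nchar(x) - 1L), t = "uri",
           dt = NA_character_, lg = NA_character_)
    } else if (startsWith(x, "_:")) {
      list(v = x, t = "blank", dt = NA_character_, lg = NA_character_)
    } else {
      body <- sub('^"((?:[^"\\\\]|\\\\.)*)".*$', "\\1", x, perl = TRUE)
      rest <- sub('^"(?:[^"\\\\]|\\\\.)*"', "", x, perl = TRUE)
      dt <- if (startsWith(rest, "^^")) substr(rest, 4, nchar(rest) - 1L)
            else NA_character_
      lg <- if (startsWith(rest, "@")) substring(rest, 2) else NA_character_
      list(v = unescape_nt_string(body), t = "literal", dt = dt, lg = lg)
    }
  }
  s <- lapply(m, function(g) term(g[2]))
  o <- lapply(m, function(g) term(g[4]))
  rdf_triples(
    subject = vapply(s, `[[`, "", "v"),
    predicate = vapply(m, function(g) substr(g[3], 2, nchar(g[3]) - 1L), ""),
    object = vapply(o, `[[`, "", "v"),
    subject_type = vapply(s, `[[`, "", "t"),
    object_type = vapply(o, `[[`, "", "t"),
    object_datatype = vapply(o, `[[`, "", "dt"),
    object_lang = vapply(o, `[[`, "", "lg")
  )
}

# ---- RDF/XML (pragmatic subset via xml2) ----

parse_rdfxml <- function(text, base = NULL) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) parse_fail("rdfxml", conditionMessage(e)))
  ns_map <- xml2::xml_ns(doc)
  if (!"xml" %in% names(ns_map)) {
    ns_map <- structure(c(as.character(ns_map),
                          "http://www.w3.org/XML/1998/namespace"),
                        names = c(names(ns_map), "xml"),
                        class = class(xml2::xml_ns(doc)))
  }
  st <- new.env(parent = emptyenv())
  st$bn <- 0L
  st$rows <- list()
  fresh_bnode <- function() { st$bn <- st$bn + 1L; paste0("_:genid", st$bn) }
  emit <- function(s, stype, p, o, otype, dt = NA_character_, lg = NA_character_) {
    st$rows[[length(st$rows) + 1L]] <- list(s, p, o, stype, otype, dt, lg)
  }
  full_name <- function(el) {
    qn <- xml2::xml_name(el, ns_map)
    if (grepl(":", qn, fixed = TRUE)) {
      parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
      uri <- unname(ns_map[parts[1]])
      if (is.na(uri)) parse_fail("rdfxml", paste0("unknown namespace prefix '",
                                                  parts[1], "'"))
      paste0(uri, paste(parts[-1], collapse = ":"))
    } else qn
  }
  attrs_of <- function(el) xml2::xml_attrs(el, ns_map)
  root <- xml2::xml_root(doc)
  rbase <- xml2::xml_attr(root, "xml:base")
  if (!is.na(rbase)) base <- rbase

  process_node <- function(el, lang = NA_character_) {
    at <- attrs_of(el)
    lang <- unname(at["xml:lang"]) %||% lang
    subj <- if (!is.na(at["rdf:about"] %||% NA)) {
      list(v = resolve_iri(unname(at["rdf:about"]), base), t = "uri")
    } else if (!is.na(at["rdf:ID"] %||% NA)) {
      list(v = resolve_iri(paste0("#", unname(at["rdf:ID"])), base), t = "uri")
    } else if (!is.na(at["rdf:nodeID"] %||% NA)) {
      list(v = paste0("_:", unname(at["rdf:nodeID"])), t = "blank")
    } else list(v = fresh_bnode(), t = "blank")
    nm <- full_name(el)
    if (nm != paste0(RDF_NS, "Description")) {
      emit(subj$v, subj$t, RDF_TYPE, nm, "uri")
    }
    skip <- c("rdf:about", "rdf:ID", "rdf:nodeID", "xml:lang", "xml:base")
    for (an in setdiff(names(at), skip)) {
      if (startsWith(an, "xmlns")) next
      p <- expand_attr(an)
      if (is.null(p)) next
      if (p == RDF_TYPE) emit(subj$v, subj$t, p, resolve_iri(unname(at[an]), base), "uri")
      else emit(subj$v, subj$t, p, unname(at[an]), "literal",
                lg = lang)
    }
    for (child in xml2::xml_children(el)) {
      process_property(child, subj, lang)
    }
    subj
  }

  expand_attr <- function(an) {
    if (!grepl(":", an, fixed = TRUE)) return(NULL)
    parts <- strsplit(an, ":", fixed = TRUE)[[1]]
    uri <- unname(ns_map[parts[1]])
    if (is.na(uri)) return(NULL)
    paste0(uri, paste(parts[-1], collapse = ":"))
  }

  process_property <- function(el, subj, lang) {
    p <- full_name(el)
    at <- attrs_of(el)
    lang <- unname(at["xml:lang"]) %||% lang
    if (!is.na(at["rdf:resource"] %||% NA)) {
      emit(subj$v, subj$t, p, resolve_iri(unname(at["rdf:resource"]), base), "uri")
      return(invisible())
    }
    if (!is.na(at["rdf:nodeID"] %||% NA)) {
      emit(subj$v, subj$t, p, paste0("_:", unname(at["rdf:nodeID"])), "blank")
      return(invisible())
    }
    pt <- unname(at["rdf:parseType"] %||% NA)
    if (!is.na(pt) && pt == "Resource") {
      b <- list(v = fresh_bnode(), t = "blank")
      emit(subj$v, subj$t, p, b$v, "blank")
      for (child in xml2::xml_children(el)) process_property(child, b, lang)
      return(invisible())
    }
    if (!is.na(pt) && pt == "Literal") {
      emit(subj$v, subj$t, p, as.character(xml2::xml_contents(el))[1] %||% "",
           "literal", dt = paste0(RDF_NS, "XMLLiteral"))
      return(invisible())
    }
    kids <- xml2::xml_children(el)
    if (length(kids) > 0) {
      obj <- process_node(kids[[1]], lang)
      emit(subj$v, subj$t, p, obj$v, obj$t)
      return(invisible())
    }
    dt <- unname(at["rdf:datatype"] %||% NA)
    val <- xml2::xml_text(el)
    emit(subj$v, subj$t, p, val, "literal",
         dt = if (is.na(dt)) NA_character_ else dt,
         lg = if (is.na(dt)) lang else NA_character_)
  }

  root_name <- full_name(root)
  if (root_name == paste0(RDF_NS, "RDF")) {
    for (child in xml2::xml_children(root)) process_node(child)
  } else {
    process_node(root)
  }
  rows <- st$rows
  if (length(rows) == 0) return(empty_graph())
  rdf_triples(
    subject = vapply(rows, `[[`, "", 1L),
    predicate = vapply(rows, `[[`, "", 2L),
    object = vapply(rows, `[[`, "", 3L),
    subject_type = vapply(rows, `[[`, "", 4L),
    object_type = vapply(rows, `[[`, "", 5L),
    object_datatype = vapply(rows, function(r) r[[6L]] %||% NA_character_, ""),
    object_lang = vapply(rows, function(r) r[[7L]] %||% NA_character_, "")
  )
}

# ---- JSON-LD (subset: inline @context with prefix/term maps; no remote
# contexts, no @list/@container reification) ----

parse_jsonld <- function(text, base = NULL) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e) parse_fail("jsonld", conditionMessage(e)))
  st <- new.env(parent = emptyenv())
  st$bn <- 0L; st$rows <- list()
  fresh_bnode <- function() { st$bn <- st$bn + 1L; paste0("_:genid", st$bn) }
  emit <- function(s, stype, p, o, otype, dt = NA_character_, lg = NA_character_) {
    st$rows[[length(st$rows) + 1L]] <- list(s, p, o, stype, otype, dt, lg)
  }

  build_ctx <- function(ctx_raw, parent = list(terms = list(), vocab = NULL,
                                               base = base)) {
    ctx <- parent
    if (is.null(ctx_raw)) return(ctx)
    if (!is.list(ctx_raw)) parse_fail("jsonld",
      "remote or non-object @context values are not supported")
    for (k in names(ctx_raw)) {
      v <- ctx_raw[[k]]
      if (k == "@vocab") { ctx$vocab <- v; next }
      if (k == "@base") { ctx$base <- v; next }
      if (startsWith(k, "@")) next
      if (is.character(v)) ctx$terms[[k]] <- list(id = v, type = NULL)
      else if (is.list(v)) ctx$terms[[k]] <- list(id = v[["@id"]] %||% k,
                                                  type = v[["@type"]] %||% NULL)
    }
    ctx
  }

  expand <- function(name, ctx, vocab_fallback = TRUE) {
    if (is.null(name) || startsWith(name, "@")) return(NULL)
    compact <- function(id) {
      # a compact IRI whose prefix is a context term expands first
      if (grepl(":", id, fixed = TRUE)) {
        ptd <- ctx$terms[[sub(":.*$", "", id)]]
        if (!is.null(ptd)) return(paste0(ptd$id, sub("^[^:]*:", "", id)))
      }
      id
    }
    td <- ctx$terms[[name]]
    if (!is.null(td)) {
      id <- compact(td$id)
      if (!is_absolute_iri(id)) id <- expand(id, ctx) %||% id
      return(id)
    }
    if (grepl(":", name, fixed = TRUE)) {
      ex <- compact(name)
      if (ex != name || is_absolute_iri(ex)) return(ex)
    }
    if (vocab_fallback && !is.null(ctx$vocab)) return(paste0(ctx$vocab, name))
    NULL
  }

  expand_id <- function(id, ctx) {
    if (startsWith(id, "_:")) return(list(v = id, t = "blank"))
    ex <- expand(id, ctx, vocab_fallback = FALSE)
    if (!is.null(ex) && is_absolute_iri(ex)) return(list(v = ex, t = "uri"))
    list(v = resolve_iri(id, ctx$base), t = "uri")
  }

  process_node <- function(obj, ctx) {
    ctx <- build_ctx(obj[["@context"]], ctx)
    subj <- if (!is.null(obj[["@id"]])) expand_id(obj[["@id"]], ctx)
            else list(v = fresh_bnode(), t = "blank")
    types <- obj[["@type"]]
    if (!is.null(types)) {
      if (!is.list(types)) types <- as.list(types)
      for (ty in types) {
        tu <- expand(ty, ctx) %||% expand_id(ty, ctx)$v
        emit(subj$v, subj$t, RDF_TYPE, tu, "uri")
      }
    }
    for (k in names(obj)) {
      if (startsWith(k, "@")) next
      p <- expand(k, ctx)
      if (is.null(p)) next
      td_type <- ctx$terms[[k]]$type
      vals <- obj[[k]]
      if (!is.list(vals) || !is.null(names(vals))) vals <- list(vals)
      for (v in vals) process_value(subj, p, v, ctx, td_type)
    }
    subj
  }

  process_value <- function(subj, p, v, ctx, td_type) {
    if (is.list(v)) {
      if (!is.null(v[["@list"]])) parse_fail("jsonld", "@list is not supported")
      if (!is.null(v[["@value"]])) {
        val <- v[["@value"]]
        dt <- v[["@type"]]
        lg <- v[["@language"]]
        dt_uri <- if (!is.null(dt)) expand(dt, ctx) %||% dt else NA_character_
        emit(subj$v, subj$t, p, literal_lex(val),
             "literal", dt = dt_uri %||% literal_dt(val),
             lg = lg %||% NA_character_)
        return(invisible())
      }
      if (!is.null(v[["@id"]]) && length(v) <= 2) {
        obj <- expand_id(v[["@id"]], ctx)
        emit(subj$v, subj$t, p, obj$v, obj$t)
        return(invisible())
      }
      obj <- process_node(v, ctx)
      emit(subj$v, subj$t, p, obj$v, obj$t)
      return(invisible())
    }
    if (identical(td_type, "@id") && is.character(v)) {
      obj <- expand_id(v, ctx)
      emit(subj$v, subj$t, p, obj$v, obj$t)
      return(invisible())
    }
    dt <- if (!is.null(td_type) && td_type != "@id") expand(td_type, ctx) %||% td_type
          else literal_dt(v)
    emit(subj$v, subj$t, p, literal_lex(v), "literal", dt = dt)
  }

  literal_lex <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v) && v == round(v) && !is.double(v)) as.character(v)
    else as.character(v)
  }
  literal_dt <- function(v) {
    if (is.logical(v)) XSD_BOOLEAN
    else if (is.numeric(v)) {
      if (v == round(v)) paste0(XSD_NS, "integer") else paste0(XSD_NS, "double")
    } else NA_character_
  }

  top_ctx <- list(terms = list(), vocab = NULL, base = base)
  if (is.null(names(x)) && is.list(x)) {
    for (node in x) process_node(node, top_ctx)
  } else if (!is.null(x[["@graph"]])) {
    ctx <- build_ctx(x[["@context"]], top_ctx)
    for (node in x[["@graph"]]) process_node(node, ctx)
  } else {
    process_node(x, top_ctx)
  }
  rows <- st$rows
  if (length(rows) == 0) return(empty_graph())
  rdf_triples(
    subject = vapply(rows, `[[`, "", 1L),
    predicate = vapply(rows, `[[`, "", 2L),
    object = vapply(rows, `[[`, "", 3L),
    subject_type = vapply(rows, `[[`, "", 4L),
    object_type = vapply(rows, `[[`, "", 5L),
    object_datatype = vapply(rows, function(r) r[[6L]] %||% NA_character_, ""),
    object_lang = vapply(rows, function(r) r[[7L]] %||% NA_character_, "")
  )
}
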