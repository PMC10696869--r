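#' Run a SPARQL SELECT query over a triple tibble
#'
#' A deliberately small SPARQL 1.1 SELECT engine sufficient for quality
#' queries over assessment reports: `PREFIX` declarations, `SELECT
#' [DISTINCT] ?vars | *`, basic graph patterns (full triple patterns
#' separated by `.`, with `a` for `rdf:type`), and `FILTER` expressions
#' over the builtins `STR`, `STRBEFORE`, `STRAFTER`, `xsd:integer`,
#' `xsd:decimal`, comparison and arithmetic operators, `&&`, `||`, and `!`.
#' Property paths, `OPTIONAL`, `UNION`, and subqueries are out of scope.
#' Joins compare term strings; integer arithmetic in filters is exact for
#' operands below 2^53.
#'
#' @param g Triple tibble (the "store").
#' @param query SPARQL SELECT query text.
#' @return Tibble of bindings, one column per selected variable.
#' @export
sparql_select <- function(g, query) {
  q <- parse_sparql(query)
  bind <- NULL
  for (pat in q$patterns) {
    cand <- match_pattern(g, pat)
    bind <- if (is.null(bind)) cand else join_bindings(bind, cand)
    if (nrow(bind) == 0) break
  }
  if (is.null(bind)) bind <- tibble::tibble(.rows = 1)
  for (f in q$filters) {
    if (nrow(bind) == 0) break
    keep <- eval_filter(f, bind)
    bind <- bind[keep, , drop = FALSE]
  }
  vars <- if (identical(q$vars, "*")) names(bind) else q$vars
  missing <- setdiff(vars, names(bind))
  for (v in missing) bind[[v]] <- character(0)
  out <- tibble::as_tibble(bind[, vars, drop = FALSE])
  if (q$distinct) out <- dplyr::distinct(out)
  out
}

parse_sparql <- function(query) {
  prefixes <- list()
  pm <- gregexpr("(?i)PREFIX\\s+([A-Za-z0-9_-]*):\\s*<([^>]*)>", query,
                 perl = TRUE)[[1]]
  for (tok in regmatches(query, list(pm))[[1]]) {
    p <- sub("(?i)PREFIX\\s+([A-Za-z0-9_-]*):.*", "\\1", tok, perl = TRUE)
    iri <- sub(".*<([^>]*)>.*", "\\1", tok)
    prefixes[[paste0(p, ":")]] <- iri
  }
  sel <- regmatches(query, regexec(
    "(?is)SELECT\\s+(DISTINCT\\s+)?(.*?)\\s*WHERE", query, perl = TRUE))[[1]]
  if (length(sel) == 0) rlang::abort("not a SELECT query",
                                     class = "rdfqa_sparql_error")
  distinct <- grepl("DISTINCT", sel[2], ignore.case = TRUE)
  vars <- if (trimws(sel[3]) == "*") "*" else
    sub("^\\?", "", strsplit(trimws(sel[3]), "\\s+")[[1]])
  body <- regmatches(query, regexec("(?s)WHERE\\s*\\{(.*)\\}[^}]*$", query,
                                    perl = TRUE))[[1]][2]
  if (is.na(body)) rlang::abort("cannot locate WHERE block",
                                class = "rdfqa_sparql_error")

  toks <- tokenize_sparql(body)
  patterns <- list(); filters <- list()
  i <- 1L
  expand <- function(t) {
    if (startsWith(t, "?")) return(list(kind = "var", value = substring(t, 2)))
    if (startsWith(t, "<")) return(list(kind = "uri",
                                        value = substr(t, 2, nchar(t) - 1L)))
    if (t == "a") return(list(kind = "uri", value = RDF_TYPE))
    if (grepl('^["\']', t)) {
      return(list(kind = "literal",
                  value = unescape_nt_string(substr(t, 2, nchar(t) - 1L))))
    }
    cpos <- regexpr(":", t, fixed = TRUE)
    if (cpos > 0) {
      ns <- prefixes[[substr(t, 1, cpos)]]
      if (is.null(ns)) rlang::abort(paste0("undeclared prefix in '", t, "'"),
                                    class = "rdfqa_sparql_error")
      return(list(kind = "uri", value = paste0(ns, substring(t, cpos + 1L))))
    }
    rlang::abort(paste0("unexpected token '", t, "' in pattern"),
                 class = "rdfqa_sparql_error")
  }
  while (i <= length(toks)) {
    t <- toks[i]
    if (t == ".") { i <- i + 1L; next }
    if (toupper(t) == "FILTER") {
      if (toks[i + 1L] != "(") rlang::abort("FILTER must be parenthesized",
                                            class = "rdfqa_sparql_error")
      depth <- 0L; j <- i + 1L
      repeat {
        if (toks[j] == "(") depth <- depth + 1L
        if (toks[j] == ")") depth <- depth - 1L
        if (depth == 0L) break
        j <- j + 1L
        if (j > length(toks)) rlang::abort("unbalanced FILTER parentheses",
                                           class = "rdfqa_sparql_error")
      }
      filters[[length(filters) + 1L]] <-
        compile_filter(toks[(i + 2L):(j - 1L)], prefixes)
      i <- j + 1L
      next
    }
    if (i + 2L > length(toks)) rlang::abort("incomplete triple pattern",
                                            class = "rdfqa_sparql_error")
    patterns[[length(patterns) + 1L]] <-
      list(s = expand(toks[i]), p = expand(toks[i + 1L]),
           o = expand(toks[i + 2L]))
    i <- i + 3L
  }
  list(prefixes = prefixes, distinct = distinct, vars = vars,
       patterns = patterns, filters = filters)
}

SPARQL_TOKEN_RE <- paste0(
  "(?s)",
  '"(?:[^"\\\\\\n]|\\\\.)*"', "|",
  "'(?:[^'\\\\\\n]|\\\\.)*'", "|",
  "<[^<>\"{}|^`\\\\\\x00-\\x20]*>", "|",
  "\\?[A-Za-z_][A-Za-z0-9_]*", "|",
  "(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_.-]*", "|",
  "[0-9]+(?:\\.[0-9]+)?", "|",
  "[A-Za-z][A-Za-z0-9_]*", "|",
  ">=|<=|!=|&&|\\|\\|", "|",
  "[][(),.!*+/<>=-]"
)

tokenize_sparql <- function(text) {
  m <- gregexpr(SPARQL_TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  toks <- regmatches(text, list(m))[[1]]
  toks[nzchar(toks)]
}

match_pattern <- function(g, pat) {
  keep <- rep(TRUE, nrow(g))
  if (pat$s$kind != "var") {
    keep <- keep & g$subject == pat$s$value & g$subject_type == "uri"
  }
  if (pat$p$kind != "var") keep <- keep & g$predicate == pat$p$value
  if (pat$o$kind == "uri") {
    keep <- keep & g$object == pat$o$value & g$object_type == "uri"
  } else if (pat$o$kind == "literal") {
    keep <- keep & g$object == pat$o$value & g$object_type == "literal"
  }
  rows <- g[keep, , drop = FALSE]
  out <- tibble::tibble(.rows = nrow(rows))
  if (pat$s$kind == "var") out[[pat$s$value]] <- rows$subject
  if (pat$p$kind == "var") out[[pat$p$value]] <- rows$predicate
  if (pat$o$kind == "var") out[[pat$o$value]] <- rows$object
  dplyr::distinct(out)
}

join_bindings <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) {
    if (nrow(a) == 0 || nrow(b) == 0) {
      return(tibble::as_tibble(c(a[0, , drop = FALSE], b[0, , drop = FALSE])))
    }
    return(tibble::as_tibble(dplyr::cross_join(a, b)))
  }
  dplyr::inner_join(a, b, by = shared, relationship = "many-to-many")
}

compile_filter <- function(toks, prefixes) {
  out <- character(length(toks))
  i <- 1L; k <- 0L
  emit <- function(x) { k <<- k + 1L; out[k] <<- x }
  while (i <= length(toks)) {
    t <- toks[i]
    if (startsWith(t, "?")) emit(paste0("`.b.`[['", substring(t, 2), "']]"))
    else if (t %in% c("xsd:integer", "xsd:decimal")) emit(".num")
    else if (toupper(t) == "STRBEFORE") emit(".strbefore")
    else if (toupper(t) == "STRAFTER") emit(".strafter")
    else if (toupper(t) == "STR") emit(".str")
    else if (t == "=") emit("==")
    else if (t == "&&") emit("&")
    else if (t == "||") emit("|")
    else if (grepl('^["\']', t)) {
      emit(deparse(unescape_nt_string(substr(t, 2, nchar(t) - 1L))))
    } else if (startsWith(t, "<") && nchar(t) > 1 && endsWith(t, ">")) {
      emit(deparse(substr(t, 2, nchar(t) - 1L)))
    } else if (grepl("^[A-Za-z_]+:", t)) {
      ns <- prefixes[[sub("^([A-Za-z_]*:).*", "\\1", t)]]
      if (is.null(ns)) rlang::abort(paste0("undeclared prefix in '", t, "'"),
                                    class = "rdfqa_sparql_error")
      emit(deparse(paste0(ns, sub("^[A-Za-z_]*:", "", t))))
    } else emit(t)
    i <- i + 1L
  }
  expr <- paste(out[seq_len(k)], collapse = " ")
  parse(text = expr)[[1]]
}

filter_env <- function(bind) {
  env <- new.env(parent = baseenv())
  env$.b. <- bind
  env$.num <- function(x) suppressWarnings(as.numeric(x))
  env$.str <- function(x) as.character(x)
  env$.strbefore <- function(x, sep) {
    pos <- regexpr(sep, x, fixed = TRUE)
    ifelse(pos > 0, substr(x, 1, pos - 1L), "")
  }
  env$.strafter <- function(x, sep) {
    pos <- regexpr(sep, x, fixed = TRUE)
    ifelse(pos > 0, substring(x, pos + attr(pos, "match.length")), "")
  }
  env
}

eval_filter <- function(f, bind) {
  res <- eval(f, envir = filter_env(bind))
  if (length(res) == 1) res <- rep(res, nrow(bind))
  res & !is.na(res)
}

#' Answer a bundled quality question over assessment reports
#'
#' Loads one of the three bundled SPARQL queries and runs it over the union
#' of the given report graphs plus the metric descriptor graph
#' ([fqm_graph()]), mirroring querying a triplestore loaded with the
#' reports:
#' \enumerate{
#'   \item Which resources have more than 10\% non-resolvable URIs?
#'   \item Which resources have undefined URIs, and which URIs are they?
#'   \item Which quality issues does a resource have, against which metrics,
#'     and how are those metrics defined?
#' }
#' Report graphs that do not contain a `dcat:Resource` node are skipped
#' with a validation warning (contributing empty bindings).
#'
#' @param reports A list of report graphs (triple tibbles), or one graph.
#' @param question 1, 2, or 3 — or the path to a `.rq` file.
#' @return Tibble of bindings.
#' @export
run_quality_query <- function(reports, question) {
  if (is.data.frame(reports)) reports <- list(reports)
  ok <- vapply(reports, function(g) {
    any(g$predicate == RDF_TYPE & g$object == paste0(DCAT_NS, "Resource"))
  }, logical(1))
  if (any(!ok)) {
    rlang::warn(paste0(sum(!ok),
      " report graph(s) lack a dcat:Resource node and were skipped"))
  }
  store <- rdf_union(dplyr::bind_rows(reports[ok]), fqm_graph())
  qfile <- if (is.character(question) && file.exists(question)) question
    else quality_query_file(question)
  sparql_select(store, paste(readLines(qfile, warn = FALSE), collapse = "\n"))
}

#' Path to a bundled quality query
#' @param question 1, 2, or 3.
#' @return File path of the installed `.rq` query.
#' @export
quality_query_file <- function(question) {
  fname <- switch(as.character(question),
    "1" = "q1_nonresolvable_over_10pct.rq",
    "2" = "q2_undefined_uris.rq",
    "3" = "q3_issues_with_definitions.rq",
    rlang::abort("question must be 1, 2, or 3"))
  system.file("queries", fname, package = "rdfqa", mustWork = TRUE)
}
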