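#' Specify a synthetic RDF resource with controlled error injections
#'
#' The forge builds an RDF document plus a matching offline fixture map in
#' which every error category of the six metrics can be injected in exact,
#' known counts, together with a ledger of what a correct assessor must
#' report. Three scaffold URIs are always present: an anchor resource used
#' as a generic subject/object, a well-defined `owl:ObjectProperty` used
#' for URI-valued filler triples, and a well-defined `owl:DatatypeProperty`
#' used for literal-valued filler triples.
#'
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param n_uris Total unique URIs of the document (including scaffold).
#' @param non_resolvable,non_rdf_content,non_parsable,undefined Counts of
#'   URIs injected at each cascade stage.
#' @param misplaced_class,misplaced_property Counts of class-as-predicate /
#'   property-as-object injections.
#' @param misused_datatype,misused_object Counts of datatype-property-with-
#'   URI-object / object-property-with-literal-object injections.
#' @param deprecated_class,deprecated_property Counts of deprecated terms in
#'   use (alternating between the `owl:deprecated "true"^^xsd:boolean` and
#'   the `rdf:type owl:DeprecatedClass`/`owl:DeprecatedProperty` patterns).
#' @param n_literals Total literal occurrences; must be at least
#'   `misused_object` (each of those witnesses needs one literal). `NULL`
#'   means the forced minimum.
#' @param n_blank_nodes Distinct blank nodes (one triple each).
#' @param n_triples Total triples; `NULL` means the minimum; larger values
#'   are met with filler triples that never touch injected URIs.
#' @param base Reserved, non-registrable namespace base, so accidental live
#'   HTTP can never succeed silently.
#' @return A `rdfqa_forge_spec` list.
#' @export
forge_spec <- function(seed = 1L, n_uris = 20L,
                       non_resolvable = 0L, non_rdf_content = 0L,
                       non_parsable = 0L, undefined = 0L,
                       misplaced_class = 0L, misplaced_property = 0L,
                       misused_datatype = 0L, misused_object = 0L,
                       deprecated_class = 0L, deprecated_property = 0L,
                       n_literals = NULL, n_blank_nodes = 0L,
                       n_triples = NULL,
                       base = "http://fixture.invalid/") {
  counts <- c(non_resolvable = non_resolvable,
              non_rdf_content = non_rdf_content,
              non_parsable = non_parsable, undefined = undefined,
              misplaced_class = misplaced_class,
              misplaced_property = misplaced_property,
              misused_datatype = misused_datatype,
              misused_object = misused_object,
              deprecated_class = deprecated_class,
              deprecated_property = deprecated_property)
  if (any(counts < 0) || n_blank_nodes < 0) {
    rlang::abort("injection counts must be non-negative",
                 class = "rdfqa_forge_error")
  }
  if (n_uris < sum(counts) + 3) {
    rlang::abort(sprintf(
      "infeasible spec: n_uris must be at least %d (injections + 3 scaffold URIs)",
      sum(counts) + 3), class = "rdfqa_forge_error")
  }
  if (!is.null(n_literals) && n_literals < counts[["misused_object"]]) {
    rlang::abort("n_literals below the literals forced by misused_object witnesses",
                 class = "rdfqa_forge_error")
  }
  structure(list(seed = as.integer(seed), n_uris = as.integer(n_uris),
                 counts = as.integer(counts) |> stats::setNames(names(counts)),
                 n_literals = if (is.null(n_literals)) NULL else as.integer(n_literals),
                 n_blank_nodes = as.integer(n_blank_nodes),
                 n_triples = if (is.null(n_triples)) NULL else as.integer(n_triples),
                 base = base),
            class = "rdfqa_forge_spec")
}

#' Forge a synthetic RDF resource, fixture map, and expected-result ledger
#'
#' Injection semantics mirror the metric definitions: non-resolvable URIs
#' map to 404 in the fixture map; non-parsable URIs map to 200 with an RDF
#' media type and garbage bytes; undefined URIs map to a parsable graph
#' omitting the URI; misplacement/misuse injections declare the term's
#' class/property flavor in its definition graph and emit a violating
#' triple in the document; deprecation injections use the standard triple
#' patterns; all remaining URIs resolve to 200 with self-defining graphs.
#' Injections are placed before filler, and the ledger is exactly what a
#' correct assessor must report. Identical specs produce byte-identical
#' Turtle.
#'
#' @param spec A [forge_spec()].
#' @return List with `document` (triple tibble), `turtle` (serialized
#'   text), `fixture_map` (named list for [offline_transport()]), and
#'   `ledger` (injected URI sets, expected inventory, expected metric
#'   results).
#' @export
forge_resource <- function(spec) {
  stopifnot(inherits(spec, "rdfqa_forge_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- spec$n_uris
  uris <- paste0(spec$base, "term/t", sprintf("%05d", seq_len(n)))
  perm <- sample.int(n)
  counts <- spec$counts
  take <- function(k) {
    if (k == 0) return(character())
    idx <- perm[seq_len(k)]
    perm <<- perm[-seq_len(k)]
    uris[idx]
  }
  inj <- purrr::imap(as.list(counts), function(k, nm) take(k))
  anchor <- take(1); pred_link <- take(1); pred_note <- take(1)
  clean <- uris[perm]

  trp <- list()
  add <- function(s, p, o) trp[[length(trp) + 1L]] <<- list(s, p, o)

  for (u in inj$non_resolvable) add(u, pred_link, anchor)
  for (u in inj$non_rdf_content) add(u, pred_link, anchor)
  for (u in inj$non_parsable) add(u, pred_link, anchor)
  for (u in inj$undefined) add(u, pred_link, anchor)
  for (u in inj$misplaced_class) add(anchor, u, anchor)
  for (u in inj$misplaced_property) add(anchor, pred_link, u)
  for (u in inj$misused_datatype) add(anchor, u, anchor)
  for (i in seq_along(inj$misused_object)) {
    add(anchor, inj$misused_object[i], lit(sprintf("misused value %03d", i)))
  }
  for (u in inj$deprecated_class) add(anchor, pred_link, u)
  for (u in inj$deprecated_property) add(anchor, u, anchor)

  present <- unique(unlist(purrr::map(trp, function(t) {
    c(t[[1]], t[[2]], if (!inherits(t[[3]], "rdfqa_literal")) t[[3]])
  })))
  need <- setdiff(c(anchor, pred_link, pred_note, clean), present)
  # scaffold presence first; the scaffold properties must never occupy an
  # object slot (a property used as object would be a misplaced-property
  # error), so they appear as subject/predicate only
  if (any(c(anchor, pred_link, pred_note) %in% need)) {
    add(pred_note, pred_link, anchor)
    need <- setdiff(need, c(anchor, pred_link, pred_note))
  }

  forced_literals <- counts[["misused_object"]]
  target_literals <- spec$n_literals %||% forced_literals
  lit_budget <- target_literals - forced_literals
  li <- 0L
  # presence singles carrying a literal, while budget lasts
  while (lit_budget > 0 && length(need) > 0) {
    u <- need[1]; need <- need[-1]
    li <- li + 1L
    add(u, pred_note, lit(sprintf("filler literal %03d", li)))
    lit_budget <- lit_budget - 1L
  }
  # pair up the rest through the link property
  while (length(need) >= 2) {
    add(need[1], pred_link, need[2])
    need <- need[-(1:2)]
  }
  if (length(need) == 1) add(need[1], pred_link, anchor)
  # remaining literal deficit as anchor padding
  while (lit_budget > 0) {
    li <- li + 1L
    add(anchor, pred_note, lit(sprintf("filler literal %03d", li)))
    lit_budget <- lit_budget - 1L
  }
  for (b in seq_len(spec$n_blank_nodes)) {
    add(sprintf("_:bn%03d", b), pred_link, anchor)
  }

  doc <- triples_from_list(trp)
  if (!is.null(spec$n_triples)) {
    if (nrow(doc) > spec$n_triples) {
      rlang::abort(sprintf(
        "infeasible spec: at least %d triples required, n_triples = %d",
        nrow(doc), spec$n_triples), class = "rdfqa_forge_error")
    }
    safe <- c(anchor, clean)  # never a property in a filler object slot
    pads <- expand.grid(s = safe, o = safe, stringsAsFactors = FALSE)
    pi <- 1L
    while (nrow(doc) < spec$n_triples) {
      if (pi > nrow(pads)) {
        rlang::abort("infeasible spec: not enough distinct filler triples available",
                     class = "rdfqa_forge_error")
      }
      cand <- triples_from_list(list(list(pads$s[pi], pred_link, pads$o[pi])))
      doc2 <- rdf_union(doc, cand)
      if (nrow(doc2) > nrow(doc)) doc <- doc2
      pi <- pi + 1L
    }
  }

  fixture_map <- forge_fixture_map(spec, inj, anchor, pred_link, pred_note,
                                   clean)
  ledger <- forge_ledger(spec, inj, doc, pred_link, pred_note)
  list(document = doc,
       turtle = rdf_serialize(doc, "turtle",
                              prefixes = c(fx = paste0(spec$base, "term/"))),
       fixture_map = fixture_map, ledger = ledger)
}

forge_fixture_map <- function(spec, inj, anchor, pred_link, pred_note, clean) {
  ttl <- function(...) paste0(..., collapse = " ")
  ent <- function(status, content_type, body) {
    list(status = status, content_type = content_type, body = body)
  }
  self_def <- function(u, extra = "") {
    ent(200L, "text/turtle",
        paste0("<", u, "> <", RDFS_LABEL, "> \"forged term\" .\n", extra))
  }
  typed <- function(u, types, deprecated_pattern = NULL) {
    lines <- paste0("<", u, "> <", RDF_TYPE, "> <", types, "> .")
    if (!is.null(deprecated_pattern)) lines <- c(lines, deprecated_pattern)
    ent(200L, "text/turtle", paste(lines, collapse = "\n"))
  }
  map <- list()
  map[[anchor]] <- self_def(anchor)
  map[[pred_link]] <- typed(pred_link, OWL_OBJECT_PROPERTY)
  map[[pred_note]] <- typed(pred_note, OWL_DATATYPE_PROPERTY)
  for (u in clean) map[[u]] <- self_def(u)
  for (u in inj$non_resolvable) {
    map[[u]] <- ent(404L, "text/plain", "not found")
  }
  for (u in inj$non_rdf_content) {
    map[[u]] <- ent(200L, "text/html",
                    "<html><body>a web page, not RDF</body></html>")
  }
  for (u in inj$non_parsable) {
    map[[u]] <- ent(200L, "text/turtle", "@@@@ not parseable as turtle @@@@")
  }
  for (u in inj$undefined) {
    map[[u]] <- ent(200L, "text/turtle",
                    paste0("<", u, "-sibling> <", RDFS_LABEL,
                           "> \"a graph omitting the requested URI\" ."))
  }
  for (u in inj$misplaced_class) map[[u]] <- typed(u, OWL_CLASS)
  for (u in inj$misplaced_property) map[[u]] <- typed(u, OWL_OBJECT_PROPERTY)
  for (u in inj$misused_datatype) map[[u]] <- typed(u, OWL_DATATYPE_PROPERTY)
  for (u in inj$misused_object) map[[u]] <- typed(u, OWL_OBJECT_PROPERTY)
  dep_pattern <- function(u, kind, i) {
    if (i %% 2 == 1) {
      paste0("<", u, "> <", OWL_DEPRECATED, "> \"true\"^^<", XSD_BOOLEAN, "> .")
    } else {
      paste0("<", u, "> <", RDF_TYPE, "> <",
             if (kind == "class") OWL_DEPRECATED_CLASS else OWL_DEPRECATED_PROP,
             "> .")
    }
  }
  for (i in seq_along(inj$deprecated_class)) {
    u <- inj$deprecated_class[i]
    map[[u]] <- typed(u, OWL_CLASS, dep_pattern(u, "class", i))
  }
  for (i in seq_along(inj$deprecated_property)) {
    u <- inj$deprecated_property[i]
    map[[u]] <- typed(u, OWL_OBJECT_PROPERTY, dep_pattern(u, "property", i))
  }
  map
}

forge_ledger <- function(spec, inj, doc, pred_link, pred_note) {
  counts <- spec$counts
  n_uris <- spec$n_uris
  n_classes <- counts[["misplaced_class"]] + counts[["deprecated_class"]]
  n_props <- 2L + counts[["misplaced_property"]] +
    counts[["misused_datatype"]] + counts[["misused_object"]] +
    counts[["deprecated_property"]]
  sets <- list(
    non_resolvable_uris = sort(inj$non_resolvable),
    non_parsable_uris = sort(inj$non_parsable),
    undefined_uris = sort(inj$undefined),
    misplaced_classes_or_properties =
      sort(c(inj$misplaced_class, inj$misplaced_property)),
    misused_datatype_or_object_property =
      sort(c(inj$misused_datatype, inj$misused_object)),
    deprecated_classes_or_properties =
      sort(c(inj$deprecated_class, inj$deprecated_property)))
  denoms <- c(n_uris, n_uris, n_uris, n_classes + n_props, n_props,
              n_classes + n_props)
  metrics <- purrr::map2(sets, denoms, function(s, d) {
    affected <- sum(triples_mentioning(doc, s))
    tibble::tibble(n_errors = length(s), denominator = d,
                   value = sprintf("%d/%d", length(s), d),
                   affected_triples = affected, total_triples = nrow(doc),
                   error_uris = list(s))
  })
  expected_metrics <- dplyr::bind_rows(metrics, .id = "metric_id")
  list(
    injected = inj,
    scaffold = list(pred_link = pred_link, pred_note = pred_note),
    expected_inventory = tibble::tibble(
      n_uris = n_uris,
      n_literals = sum(doc$object_type == "literal"),
      n_blank_nodes = spec$n_blank_nodes,
      n_triples = nrow(doc)),
    expected_metrics = expected_metrics,
    non_rdf_content = sort(inj$non_rdf_content))
}

#' Write forge outputs to a directory
#'
#' Writes `resource.ttl`, `fixtures.json`, and `ledger.json`, the on-disk
#' form consumed by the command-line `assess --offline-map` mode.
#'
#' @param forged Result of [forge_resource()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
forge_write <- function(forged, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(forged$turtle, file.path(dir, "resource.ttl"))
  jsonlite::write_json(forged$fixture_map, file.path(dir, "fixtures.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  led <- forged$ledger
  led$expected_inventory <- as.list(led$expected_inventory)
  led$expected_metrics <- purrr::transpose(led$expected_metrics)
  jsonlite::write_json(led, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
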