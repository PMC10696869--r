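# Shared fixture builders: tiny graphs, fixture-map entries, and randomized
# forge specs. Everything is generated in code; no binary fixtures.

`%||%` <- function(a, b) if (is.null(a)) b else a

NS <- list(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  xsd = "http://www.w3.org/2001/XMLSchema#",
  dqv = "http://www.w3.org/ns/dqv#",
  dcat = "http://www.w3.org/ns/dcat#",
  dct = "http://purl.org/dc/terms/",
  skos = "http://www.w3.org/2004/02/skos/core#",
  fqm = "http://purl.org/fqm#",
  ex = "http://example.invalid/ns/"
)

uri_triple <- function(s, p, o) {
  rdf_triples(subject = s, predicate = p, object = o,
              subject_type = ifelse(startsWith(s, "_:"), "blank", "uri"),
              object_type = ifelse(startsWith(o, "_:"), "blank", "uri"))
}

lit_triple <- function(s, p, o, datatype = NA_character_,
                       lang = NA_character_) {
  rdf_triples(subject = s, predicate = p, object = o,
              object_type = "literal", object_datatype = datatype,
              object_lang = lang)
}

graph_of <- function(...) dplyr::distinct(dplyr::bind_rows(...))

# fixture-map entry: 200 + turtle body defining `uri` with the given extra
# turtle lines (absolute IRIs only)
fx_turtle <- function(body) list(status = 200L, content_type = "text/turtle",
                                 body = body)

fx_self <- function(uri) {
  fx_turtle(paste0("<", uri, "> <", NS$rdfs, "label> \"defined term\" ."))
}

fx_typed <- function(uri, ..., extra = character()) {
  types <- c(...)
  fx_turtle(paste(c(
    paste0("<", uri, "> <", NS$rdf, "type> <", types, "> ."), extra),
    collapse = "\n"))
}

# map every URI of a document to a defined self-description, then override
self_defining_map <- function(uris, overrides = list()) {
  map <- stats::setNames(lapply(uris, fx_self), uris)
  utils::modifyList(map, overrides)
}

# assess an in-memory document offline, against a fixture map or a
# ready-made transport function
assess_offline <- function(doc, map, ...) {
  tr <- if (is.function(map)) map else offline_transport(map, strict = FALSE)
  rdf_assess(doc, transport = tr,
             generated_at = as.POSIXct("2022-12-30", tz = "UTC"), ...)
}

metric_row <- function(a, id) {
  m <- tidy(a)
  m[m$metric_id == id, ]
}

# randomized forge spec drawn from a seeded stream; sizes kept at desk scale
random_forge_spec <- function(seed, max_category = 4L, min_filler = 5L,
                              max_filler = 40L) {
  set.seed(seed)
  cnt <- function() sample(0:max_category, 1)
  counts <- list(
    non_resolvable = cnt(), non_rdf_content = cnt(), non_parsable = cnt(),
    undefined = cnt(), misplaced_class = cnt(), misplaced_property = cnt(),
    misused_datatype = cnt(), misused_object = cnt(),
    deprecated_class = cnt(), deprecated_property = cnt())
  filler <- sample(min_filler:max_filler, 1)
  n_uris <- sum(unlist(counts)) + 3L + filler
  do.call(forge_spec, c(list(seed = seed, n_uris = n_uris,
                             n_literals = counts$misused_object +
                               sample(0:8, 1),
                             n_blank_nodes = sample(0:3, 1)),
                        counts))
}

expect_assessment_matches_ledger <- function(forged, a) {
  led <- forged$ledger$expected_metrics
  got <- tidy(a)
  for (i in seq_len(nrow(led))) {
    id <- led$metric_id[i]
    g <- got[got$metric_id == id, ]
    expect_equal(g$n_errors, led$n_errors[i], info = id)
    expect_equal(g$denominator, led$denominator[i], info = id)
    expect_equal(g$affected_triples, led$affected_triples[i], info = id)
    expect_identical(sort(g$error_uris[[1]]), led$error_uris[[i]], info = id)
  }
  inv <- forged$ledger$expected_inventory
  expect_equal(a$inventory$n_uris, inv$n_uris)
  expect_equal(a$inventory$n_literals, inv$n_literals)
  expect_equal(a$inventory$n_blank_nodes, inv$n_blank_nodes)
  expect_equal(a$inventory$n_triples, inv$n_triples)
}
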