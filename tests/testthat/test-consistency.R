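# Term typing, deprecation patterns, misplacement, and flavor misuse.

typings_for <- function(doc, map, ...) {
  out <- resolve_uris(rdf_inventory(doc)$unique_uris[[1]],
                      offline_transport(map), retries = 0)
  casc <- cascade_verdicts(out)
  type_terms(casc$verdicts, casc$graphs, ...)
}

test_that("class and property typing derives from the definition graph only", {
  doc <- graph_of(
    uri_triple("http://e/s", "http://e/objProp", "http://e/o"),
    uri_triple("http://e/s", "http://e/p", "http://e/cls"),
    uri_triple("http://e/s", "http://e/p", "http://e/both"))
  map <- self_defining_map(c("http://e/s", "http://e/o", "http://e/p"))
  map[["http://e/objProp"]] <- fx_typed("http://e/objProp",
                                        paste0(NS$owl, "ObjectProperty"))
  # typed both rdfs:Class and owl:Class: a class once, idempotently
  map[["http://e/cls"]] <- fx_typed("http://e/cls", paste0(NS$owl, "Class"),
                                    paste0(NS$rdfs, "Class"))
  map[["http://e/both"]] <- fx_typed("http://e/both", paste0(NS$owl, "Class"),
                                     paste0(NS$owl, "ObjectProperty"))
  ty <- typings_for(doc, map)
  row <- function(u) ty[ty$uri == u, ]
  expect_true(row("http://e/objProp")$is_property)
  expect_equal(row("http://e/objProp")$flavor, "object")
  expect_false(row("http://e/objProp")$is_class)
  expect_true(row("http://e/cls")$is_class)
  expect_equal(sum(ty$uri == "http://e/cls"), 1L)
  # punning: evaluated under both rule families
  expect_true(row("http://e/both")$is_class &&
                row("http://e/both")$is_property)
})

test_that("each deprecation pattern flips the flag; near-misses do not", {
  u <- "http://e/term"
  dep_graph <- function(extra) {
    rdf_parse_string(paste(c(
      paste0("<", u, "> <", NS$rdf, "type> <", NS$owl, "Class> ."), extra),
      collapse = "\n"), "turtle")
  }
  pattern <- function(s) paste0("<", u, "> ", s, " .")
  flips <- c(
    pattern(paste0("<", NS$owl, "deprecated> \"true\"^^<", NS$xsd, "boolean>")),
    pattern(paste0("<", NS$rdf, "type> <", NS$owl, "DeprecatedClass>")),
    pattern(paste0("<", NS$rdf, "type> <", NS$owl, "DeprecatedProperty>")))
  keeps <- c(
    pattern(paste0("<", NS$owl, "deprecated> \"false\"^^<", NS$xsd, "boolean>")),
    pattern(paste0("<", NS$owl, "deprecated> \"true\"")),   # untyped literal
    pattern(paste0("<", NS$owl, "deprecated> \"True\"^^<", NS$xsd, "boolean>")),
    "<http://e/other> <http://www.w3.org/2002/07/owl#deprecated> \"true\"^^<http://www.w3.org/2001/XMLSchema#boolean> .")
  for (x in flips) expect_true(check_deprecated(u, dep_graph(x)), info = x)
  for (x in keeps) expect_false(check_deprecated(u, dep_graph(x)), info = x)
})

test_that("a class used as predicate is misplaced; as subject or object it is not", {
  catalog <- paste0(NS$dcat, "Catalog")
  doc <- graph_of(
    uri_triple("http://e/s", catalog, "http://e/o"),
    uri_triple(catalog, "http://e/p", "http://e/o"),
    uri_triple("http://e/s", paste0(NS$rdf, "type"), catalog))
  typings <- tibble::tibble(uri = catalog, is_class = TRUE,
                            is_property = FALSE, flavor = "none",
                            deprecated = FALSE, is_named_individual = FALSE)
  errs <- find_misplaced_classes(doc, typings)
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$predicate, catalog)
  doc_lines <- strsplit(rdf_serialize(doc, "ntriples"), "\n")[[1]]
  expect_true(errs$witness %in% doc_lines)  # witness occurs in the document
})

test_that("properties as objects are misplaced except under defining predicates", {
  p <- "http://e/prop"
  typings <- tibble::tibble(uri = p, is_class = FALSE, is_property = TRUE,
                            flavor = "object", deprecated = FALSE,
                            is_named_individual = FALSE)
  doc <- graph_of(
    uri_triple(p, paste0(NS$rdf, "type"), paste0(NS$owl, "ObjectProperty")),
    uri_triple(p, paste0(NS$rdfs, "subPropertyOf"), p),
    uri_triple("http://e/s", "http://e/uses", p))
  errs <- find_misplaced_properties(doc, typings)
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$predicate, "http://e/uses")
  # exempting the predicate removes exactly that error and no others
  errs2 <- find_misplaced_properties(doc, typings,
                                     defining = c(defining_predicates(),
                                                  "http://e/uses"))
  expect_equal(nrow(errs2), 0L)
})

test_that("object-property misuse matches the published worked examples", {
  media_type <- paste0(NS$dcat, "mediaType")
  close_match <- paste0(NS$skos, "closeMatch")
  doc <- graph_of(
    lit_triple("http://data.wikipathways.org/20220410/rdf/wp", media_type,
               "application/zip"),
    lit_triple("http://purl.obolibrary.org/obo/RO_0002436", close_match,
               "http://purl.obolibrary.org/obo/MI_0915"))
  typings <- tibble::tibble(uri = c(media_type, close_match),
                            is_class = FALSE, is_property = TRUE,
                            flavor = "object", deprecated = FALSE,
                            is_named_individual = FALSE)
  errs <- find_misused_property_flavors(doc, typings)
  expect_equal(sort(errs$uri), sort(c(media_type, close_match)))
  expect_true(all(errs$kind == "misused_object_property"))
  # replacing the quoted-literal object with a real URI clears the flag
  doc_fixed <- graph_of(
    lit_triple("http://data.wikipathways.org/20220410/rdf/wp", media_type,
               "application/zip"),
    uri_triple("http://purl.obolibrary.org/obo/RO_0002436", close_match,
               "http://purl.obolibrary.org/obo/MI_0915"))
  errs2 <- find_misused_property_flavors(doc_fixed, typings)
  expect_equal(errs2$uri, media_type)
})

test_that("datatype-property misuse and blank-node exemption behave as defined", {
  d <- "http://e/dtProp"; o <- "http://e/objProp"
  typings <- tibble::tibble(uri = c(d, o), is_class = FALSE,
                            is_property = TRUE,
                            flavor = c("datatype", "object"),
                            deprecated = FALSE, is_named_individual = FALSE)
  doc <- graph_of(
    uri_triple("http://e/s", d, "http://e/target"),      # URI via datatype
    lit_triple("http://e/s", d, "fine"),                 # literal is correct
    uri_triple("http://e/s", o, "_:b1"),                 # blank node object
    uri_triple("http://e/s2", d, "_:b2"))
  errs <- find_misused_property_flavors(doc, typings)
  expect_equal(nrow(errs), 1L)
  expect_equal(errs$kind, "misused_datatype_property")
  expect_equal(errs$object, "http://e/target")
})

test_that("annotation properties are exempt from the misuse rules", {
  a <- "http://e/annProp"
  typings <- tibble::tibble(uri = a, is_class = FALSE, is_property = TRUE,
                            flavor = "annotation", deprecated = FALSE,
                            is_named_individual = FALSE)
  doc <- graph_of(lit_triple("http://e/s", a, "text"),
                  uri_triple("http://e/s", a, "http://e/o"))
  expect_equal(nrow(find_misused_property_flavors(doc, typings)), 0L)
})

test_that("named individuals are exempt from the consistency checks", {
  ni <- "http://purl.obolibrary.org/obo/IAO_0000120"
  doc <- graph_of(uri_triple("http://e/s", ni, "http://e/o"))
  map <- self_defining_map(c("http://e/s", "http://e/o"))
  map[[ni]] <- fx_typed(ni, paste0(NS$owl, "NamedIndividual"))
  ty <- typings_for(doc, map)
  expect_true(ty$is_named_individual[ty$uri == ni])
  a <- assess_offline(doc, map)
  expect_equal(sum(tidy(a)$n_errors), 0L)
  # and it does not enter the class/property denominators
  m <- metric_row(a, "misused_datatype_or_object_property")
  expect_equal(m$denominator, 0L)
})

test_that("deprecated terms in use are reported and still consistency-checked", {
  dp <- "http://e/depProp"
  doc <- graph_of(lit_triple("http://e/s", dp, "oops"))  # object prop + literal
  map <- self_defining_map("http://e/s")
  map[[dp]] <- fx_typed(dp, paste0(NS$owl, "ObjectProperty"),
                        extra = paste0("<", dp, "> <", NS$owl,
                                       "deprecated> \"true\"^^<", NS$xsd,
                                       "boolean> ."))
  a <- assess_offline(doc, map)
  expect_equal(metric_row(a, "deprecated_classes_or_properties")$n_errors, 1L)
  expect_equal(metric_row(a, "misused_datatype_or_object_property")$n_errors,
               1L)
})
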