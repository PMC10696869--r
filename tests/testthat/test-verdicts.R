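# The five-stage verdict cascade: non_resolvable, non_rdf_content,
# non_parsable, undefined, defined.

cascade_for <- function(doc, map, ...) {
  out <- resolve_uris(rdf_inventory(doc)$unique_uris[[1]],
                      offline_transport(map), retries = 0)
  cascade_verdicts(out, ...)
}

stage_of <- function(casc, uri) casc$verdicts$stage[casc$verdicts$uri == uri]

test_that("parse_retrieved_content requires at least one triple of the declared type", {
  expect_equal(nrow(parse_retrieved_content(
    "<http://e/a> <http://e/b> <http://e/c> .", "text/turtle")), 1L)
  expect_null(parse_retrieved_content("not xml at all", "application/rdf+xml"))
  expect_null(parse_retrieved_content("", "text/turtle"))       # zero triples
  expect_null(parse_retrieved_content("# only a comment", "text/turtle"))
  # declared media type decides the parser: turtle served as rdf+xml fails
  expect_null(parse_retrieved_content(
    "@prefix ex: <http://e/> . ex:a ex:b ex:c .", "application/rdf+xml"))
  # prose served as text/plain must fail the strict N-Triples parser
  expect_null(parse_retrieved_content("This is a README.", "text/plain"))
  expect_equal(nrow(parse_retrieved_content(
    "<http://e/a> <http://e/b> \"x\" .", "text/plain")), 1L)
})

test_that("a term present in a sibling-heavy namespace document is still undefined", {
  # the namespace document defines Resource but not source
  rdfs_doc <- fx_turtle(paste0(
    "<", NS$rdfs, "Resource> <", NS$rdf, "type> <", NS$rdfs, "Class> .\n",
    "<", NS$rdfs, "label> <", NS$rdf, "type> <", NS$rdf, "Property> ."))
  doc <- graph_of(
    uri_triple("http://e/s", paste0(NS$rdfs, "source"), "http://e/o"),
    uri_triple("http://e/s", paste0(NS$rdf, "type"), paste0(NS$rdfs, "Resource")))
  map <- self_defining_map(c("http://e/s", "http://e/o"))
  # fixture keys are defragmented request URIs: hash URIs share a document
  map[[sub("#$", "", NS$rdfs)]] <- rdfs_doc
  map[[sub("#$", "", NS$rdf)]] <- fx_turtle(paste0(
    "<", NS$rdf, "type> <", NS$rdf, "type> <", NS$rdf, "Property> ."))
  casc <- cascade_for(doc, map)
  expect_equal(stage_of(casc, paste0(NS$rdfs, "source")), "undefined")
  expect_equal(stage_of(casc, paste0(NS$rdfs, "Resource")), "defined")
})

test_that("hashless URIs are not defined by their hash variant (syntactic matching)", {
  provo <- "http://e/ns/prov-o"
  body <- fx_turtle(paste0("<", provo, "#> <", NS$rdf, "type> <", NS$owl,
                           "Ontology> ."))
  doc <- uri_triple("http://e/s", "http://e/p", provo)
  map <- self_defining_map(c("http://e/s", "http://e/p"))
  map[[provo]] <- body
  casc <- cascade_for(doc, map)
  expect_equal(stage_of(casc, provo), "undefined")
})

test_that("misspelled terms in an otherwise fine vocabulary are undefined", {
  dct_doc <- fx_turtle(paste0(
    "<", NS$dct, "accrualPeriodicity> <", NS$rdf, "type> <", NS$rdf,
    "Property> ."))
  typo <- paste0(NS$dct, "accuralPeriodicity")
  doc <- uri_triple("http://e/s", typo, "http://e/o")
  map <- self_defining_map(c("http://e/s", "http://e/o"))
  map[[typo]] <- dct_doc
  casc <- cascade_for(doc, map)
  expect_equal(stage_of(casc, typo), "undefined")
})

test_that("the cascade assigns exactly one stage and stops early as specified", {
  uris <- paste0("http://e/", c("dead", "page", "garbled", "ghost", "fine"))
  doc <- graph_of(purrr::map(uris, function(u)
    uri_triple(u, "http://e/p", "http://e/fine")))
  map <- self_defining_map(c(uris, "http://e/p"))
  map[["http://e/dead"]] <- list(status = 404)
  map[["http://e/page"]] <- list(status = 200, content_type = "text/html",
                                 body = "<html>hi</html>")
  map[["http://e/garbled"]] <- list(status = 200,
                                    content_type = "application/rdf+xml",
                                    body = "not xml at all")
  map[["http://e/ghost"]] <- fx_turtle(
    "<http://e/other> <http://e/p> \"o\" .")
  casc <- cascade_for(doc, map)
  expect_equal(stage_of(casc, "http://e/dead"), "non_resolvable")
  expect_equal(stage_of(casc, "http://e/page"), "non_rdf_content")
  expect_equal(stage_of(casc, "http://e/garbled"), "non_parsable")
  expect_equal(stage_of(casc, "http://e/ghost"), "undefined")
  expect_equal(stage_of(casc, "http://e/fine"), "defined")
  # partition: each URI exactly one verdict
  expect_equal(sort(casc$verdicts$uri), sort(rdf_unique_uris(doc)))
  expect_equal(anyDuplicated(casc$verdicts$uri), 0L)

  # non-RDF content is never an error: absent from every metric error list
  a <- assess_offline(doc, map)
  expect_false("http://e/page" %in% unlist(tidy(a)$error_uris))
})

test_that("flipping one fixture entry to 404 moves only that URI", {
  uris <- paste0("http://e/t", 1:6)
  doc <- graph_of(purrr::map(uris, function(u)
    uri_triple(u, "http://e/p", "http://e/t1")))
  map <- self_defining_map(c(uris, "http://e/p"))
  before <- cascade_for(doc, map)$verdicts
  map[["http://e/t3"]] <- list(status = 404)
  after <- cascade_for(doc, map)$verdicts
  expect_equal(after$stage[after$uri == "http://e/t3"], "non_resolvable")
  others <- before$uri != "http://e/t3"
  expect_identical(before[others, c("uri", "stage")],
                   after[others, c("uri", "stage")])
})

test_that("the subject-only mode is stricter than any-position matching", {
  u <- "http://e/term"
  body_obj <- fx_turtle(paste0("<http://e/s> <http://e/p> <", u, "> ."))
  doc <- uri_triple(u, "http://e/p", u)
  map <- self_defining_map("http://e/p")
  map[[u]] <- body_obj
  expect_equal(stage_of(cascade_for(doc, map), u), "defined")
  expect_equal(stage_of(cascade_for(doc, map, subject_only = TRUE), u),
               "undefined")
})
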