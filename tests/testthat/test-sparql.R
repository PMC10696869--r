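# The SPARQL SELECT subset engine and the bundled quality queries.

test_that("basic graph patterns join across triples", {
  g <- graph_of(
    uri_triple("http://e/a", paste0(NS$rdf, "type"), "http://e/T"),
    uri_triple("http://e/b", paste0(NS$rdf, "type"), "http://e/T"),
    lit_triple("http://e/a", "http://e/name", "alpha"),
    lit_triple("http://e/b", "http://e/name", "beta"),
    lit_triple("http://e/c", "http://e/name", "gamma"))
  res <- sparql_select(g, "
    PREFIX e: <http://e/>
    SELECT ?x ?n WHERE {
      ?x a e:T .
      ?x e:name ?n .
    }")
  expect_equal(sort(res$n), c("alpha", "beta"))
  res2 <- sparql_select(g, "
    PREFIX e: <http://e/>
    SELECT DISTINCT ?t WHERE { ?x a ?t . }")
  expect_equal(res2$t, "http://e/T")
})

test_that("filters with string builtins and arithmetic work", {
  g <- graph_of(
    lit_triple("http://e/a", "http://e/v", "3/10"),
    lit_triple("http://e/b", "http://e/v", "1/10"),
    lit_triple("http://e/c", "http://e/v", "2/30"))
  res <- sparql_select(g, '
    PREFIX e: <http://e/>
    PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>
    SELECT ?s WHERE {
      ?s e:v ?val .
      FILTER (xsd:integer(STRBEFORE(?val, "/")) * 10 >
              xsd:integer(STRAFTER(?val, "/")))
    }')
  expect_equal(sort(res$s), c("http://e/a"))
})

test_that("the fraction threshold agrees with exact rational arithmetic", {
  set.seed(99)
  n <- sample(0:1000000, 400, replace = TRUE)
  d <- sample(1:1000000, 400, replace = TRUE)
  n <- pmin(n, d)
  got <- vapply(seq_along(n), function(i)
    fraction_gt(sprintf("%d/%d", n[i], d[i]), 0.10), logical(1))
  expect_identical(got, n * 10 > d)  # exact integer cross-multiplication
  # boundary cases around exact equality
  expect_false(fraction_gt("1/10", 0.10))
  expect_false(fraction_gt("100000/1000000", 0.10))
  expect_true(fraction_gt("100001/1000000", 0.10))
  expect_false(fraction_gt("0/0", 0.10))
})

test_that("quality question 1 finds resources over the 10% threshold", {
  counts <- published_assessment_counts()
  reports <- replay_published_counts(counts[!counts$special, ])
  res <- run_quality_query(reports, 1)
  expect_equal(nrow(res), 5L)
  slugs <- c("head-and-neck-tumor-registry-austria",
             "a-biobank-of-patients-with-primary-immune-deficiencies",
             "hpscreg-vocabulary", "resource-metadata-ontology",
             "the-wikipathways-ontology")
  expect_setequal(res$resource,
                  paste0("http://example.invalid/resource/", slugs))
  # every returned value is indeed over 10%, checked independently
  expect_true(all(vapply(res$value, fraction_gt, logical(1), p = 0.10)))
})

test_that("quality question 2 lists one row per (resource, undefined URI)", {
  counts <- published_assessment_counts()
  reports <- replay_published_counts(counts)
  res <- run_quality_query(reports, 2)
  expect_equal(nrow(res), 69L)
  per_resource <- table(res$resource)
  expect_setequal(as.integer(per_resource), c(1L, 1L, 2L, 1L, 2L, 60L, 2L))
  # cross-check against a plain dplyr recount over the same store
  store <- dplyr::bind_rows(reports)
  undef_nodes <- store$subject[store$predicate ==
                                 paste0(NS$dqv, "isMeasurementOf") &
                                 store$object == paste0(NS$fqm,
                                                        "uriUndefinedMetric")]
  manual <- sum(store$subject %in% undef_nodes &
                  store$predicate == paste0(NS$dct, "relation"))
  expect_equal(nrow(res), manual)
})

test_that("quality question 3 returns failed metrics with their definitions", {
  counts <- published_assessment_counts()
  wp <- replay_published_counts(
    counts[counts$resource == "The WikiPathways Ontology", ])[[1]]
  res <- run_quality_query(wp, 3)
  expect_equal(nrow(res), 3L)
  expect_setequal(res$metric, paste0(NS$fqm, c(
    "uriNonResolvableMetric", "uriUndefinedMetric",
    "misusedPropertyTypeMetric")))
  expect_true(all(nchar(res$definition) > 20))
  # a resource failing nothing lists zero issue metrics
  clean <- replay_published_counts(counts[counts$resource == "NCIT", ])[[1]]
  expect_equal(nrow(run_quality_query(clean, 3)), 0L)
})

test_that("report graphs lacking a resource node are skipped with a warning", {
  counts <- published_assessment_counts()
  good <- replay_published_counts(counts[2, ])[[1]]
  bad <- uri_triple("http://e/x", "http://e/p", "http://e/y")
  expect_warning(res <- run_quality_query(list(good, bad), 1),
                 regexp = "skipped")
  expect_equal(nrow(res), 1L)
})

test_that("SPARQL errors are distinguishable", {
  g <- rdf_triples()
  expect_error(sparql_select(g, "ASK { ?s ?p ?o }"),
               class = "rdfqa_sparql_error")
  expect_error(sparql_select(g, "SELECT ?s WHERE { ?s ex:p ?o . }"),
               class = "rdfqa_sparql_error")
})
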