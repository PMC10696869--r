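# The fixture forge: reproducibility, ledger soundness, independence.

test_that("identical specs produce byte-identical output", {
  spec <- forge_spec(seed = 17, n_uris = 30, non_resolvable = 3,
                     undefined = 2, misused_object = 1, n_literals = 5,
                     n_blank_nodes = 2)
  f1 <- forge_resource(spec)
  f2 <- forge_resource(spec)
  expect_identical(f1$turtle, f2$turtle)
  expect_identical(f1$fixture_map, f2$fixture_map)
  expect_identical(f1$ledger$expected_metrics, f2$ledger$expected_metrics)
  # a different seed re-arranges the resource
  f3 <- forge_resource(forge_spec(seed = 18, n_uris = 30, non_resolvable = 3,
                                  undefined = 2, misused_object = 1,
                                  n_literals = 5, n_blank_nodes = 2))
  expect_false(identical(f1$turtle, f3$turtle))
})

test_that("the forge does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(forge_resource(forge_spec(seed = 9, n_uris = 10)))
  expect_identical(runif(1), before)
})

test_that("every injected error is machine-checkable on the forged artifacts", {
  forged <- forge_resource(random_forge_spec(77))
  inj <- forged$ledger$injected
  map <- forged$fixture_map
  for (u in inj$non_resolvable) {
    expect_equal(map[[u]]$status, 404L)
  }
  for (u in inj$non_rdf_content) {
    expect_false(map[[u]]$content_type %in% rdf_media_types()$media_type)
  }
  for (u in inj$non_parsable) {
    expect_true(map[[u]]$content_type %in% rdf_media_types()$media_type)
    expect_error(rdf_parse_string(map[[u]]$body, "turtle"),
                 class = "rdfqa_parse_error")
  }
  for (u in inj$undefined) {
    g <- rdf_parse_string(map[[u]]$body, "turtle")
    expect_false(u %in% rdf_unique_uris(g))
  }
  for (u in c(inj$misplaced_class, inj$deprecated_class)) {
    g <- rdf_parse_string(map[[u]]$body, "turtle")
    expect_true(any(g$subject == u & g$predicate == paste0(NS$rdf, "type") &
                      g$object == paste0(NS$owl, "Class")))
  }
  for (i in seq_along(inj$deprecated_class)) {
    g <- rdf_parse_string(map[[inj$deprecated_class[i]]]$body, "turtle")
    expect_true(check_deprecated(inj$deprecated_class[i], g))
  }
  for (i in seq_along(inj$deprecated_property)) {
    g <- rdf_parse_string(map[[inj$deprecated_property[i]]]$body, "turtle")
    expect_true(check_deprecated(inj$deprecated_property[i], g))
  }
  # every injected URI appears in the document
  doc_uris <- rdf_unique_uris(forged$document)
  expect_true(all(unlist(inj) %in% doc_uris))
})

test_that("incrementing one injection count changes exactly one numerator by one", {
  base_args <- list(seed = 55, n_uris = 40, non_resolvable = 2, undefined = 1,
                    misplaced_class = 1, misused_object = 1,
                    n_literals = 6)
  base_led <- forge_resource(do.call(forge_spec, base_args))$ledger
  bumps <- list(
    c(non_resolvable = 1), c(non_parsable = 1), c(undefined = 1),
    c(misplaced_property = 1), c(misused_datatype = 1),
    c(deprecated_class = 1))
  affected_metric <- c("non_resolvable_uris", "non_parsable_uris",
                       "undefined_uris", "misplaced_classes_or_properties",
                       "misused_datatype_or_object_property",
                       "deprecated_classes_or_properties")
  for (k in seq_along(bumps)) {
    args <- base_args
    nm <- names(bumps[[k]])
    args[[nm]] <- (args[[nm]] %||% 0L) + 1L
    led <- forge_resource(do.call(forge_spec, args))$ledger
    for (mid in affected_metric) {
      delta <- led$expected_metrics$n_errors[
        led$expected_metrics$metric_id == mid] -
        base_led$expected_metrics$n_errors[
          base_led$expected_metrics$metric_id == mid]
      expect_equal(delta, if (mid == affected_metric[k]) 1L else 0L,
                   info = paste(nm, "->", mid))
    }
  }
})

test_that("infeasible specs are rejected with clear errors", {
  expect_error(forge_spec(n_uris = 4, non_resolvable = 3),
               class = "rdfqa_forge_error")
  expect_error(forge_spec(n_uris = 20, misused_object = 3, n_literals = 1),
               class = "rdfqa_forge_error")
  expect_error(forge_spec(n_uris = 20, non_resolvable = -1),
               class = "rdfqa_forge_error")
  expect_error(forge_resource(forge_spec(n_uris = 30, n_triples = 5)),
               class = "rdfqa_forge_error")
})

test_that("forge outputs write to disk and assess from files", {
  forged <- forge_resource(forge_spec(seed = 4, n_uris = 16,
                                      non_resolvable = 2, n_literals = 3))
  dir <- tempfile()
  forge_write(forged, dir)
  expect_true(all(file.exists(file.path(dir, c("resource.ttl",
                                               "fixtures.json",
                                               "ledger.json")))))
  a <- rdf_assess(file.path(dir, "resource.ttl"),
                  offline_map = file.path(dir, "fixtures.json"),
                  generated_at = as.POSIXct("2022-12-30", tz = "UTC"))
  expect_equal(metric_row(a, "non_resolvable_uris")$value,
               sprintf("2/%d", 16))
})
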