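METRIC_IDS <- c("non_resolvable_uris", "non_parsable_uris", "undefined_uris",
                "misplaced_classes_or_properties",
                "misused_datatype_or_object_property",
                "deprecated_classes_or_properties")

#' Format a count pair the way assessment tables print it
#'
#' @param n,d Numerator and denominator.
#' @return `"n/d (p%)"` with the percentage at one decimal; a zero
#'   denominator reports 0%.
#' @export
format_cell <- function(n, d) {
  sprintf("%d/%d (%s%%)", n, d, format_pct(n, d))
}

format_pct <- function(n, d) {
  p <- if (d == 0) 0 else 100 * n / d
  sprintf("%.1f", p)
}

#' Exact comparison of a fraction string against a threshold
#'
#' Parses `"n/N"` and decides `n/N > p` in exact integer arithmetic (the
#' threshold is scaled to an integer over 10^6), so the comparison never
#' depends on floating-point rounding of the quotient.
#'
#' @param value Fraction string `"n/N"`.
#' @param p Threshold in `[0, 1]` with at most six decimal places.
#' @return Logical; `FALSE` for a zero denominator.
#' @export
fraction_gt <- function(value, p) {
  m <- regmatches(value, regexec("^\\s*([0-9]+)\\s*/\\s*([0-9]+)\\s*$", value))[[1]]
  if (length(m) == 0) rlang::abort(paste0("not an 'n/N' fraction: '", value, "'"))
  n <- as.numeric(m[2]); d <- as.numeric(m[3])
  if (d == 0) return(FALSE)
  # n * 1e6 and round(p*1e6) * d stay below 2^53: exact in doubles
  n * 1e6 > round(p * 1e6) * d
}

#' Compute the six metric results
#'
#' Denominators follow the metric definitions: the URI-level metrics
#' (non-resolvable, non-parsable, undefined) are proportions of all unique
#' URIs; misplaced and deprecated terms are proportions of the unique
#' classes and properties among the document's defined URIs; flavor misuse
#' is a proportion of all unique properties. For each metric the affected
#' triples are the document triples containing at least one of its error
#' URIs. A zero denominator yields a defined `0/0` result with a 0%
#' proportion.
#'
#' @param doc Assessed document (triple tibble).
#' @param inventory From [rdf_inventory()].
#' @param verdicts From [cascade_verdicts()].
#' @param typings From [type_terms()].
#' @param cons_errors From [find_consistency_errors()].
#' @return Tibble with one row per metric: `metric_id`, `n_errors`,
#'   `denominator`, `proportion`, `value` (the `"n/N"` string),
#'   `affected_triples`, `total_triples`, `affected_pct`, `cell`
#'   (table-style `"n/N (p%)"`), and list-column `error_uris`.
#' @export
compute_metric_results <- function(doc, inventory, verdicts, typings,
                                   cons_errors) {
  n_uris <- inventory$n_uris
  n_triples <- inventory$n_triples
  relevant <- typings[!(typings$is_named_individual & !typings$is_class &
                          !typings$is_property), ]
  n_classes <- sum(relevant$is_class)
  n_props <- sum(relevant$is_property)

  errs <- function(stages = NULL, kinds = NULL) {
    if (!is.null(stages)) {
      sort(unique(verdicts$uri[verdicts$stage %in% stages]))
    } else {
      sort(unique(cons_errors$uri[cons_errors$kind %in% kinds]))
    }
  }
  sets <- list(
    non_resolvable_uris = list(errs(stages = "non_resolvable"), n_uris),
    non_parsable_uris = list(errs(stages = "non_parsable"), n_uris),
    undefined_uris = list(errs(stages = "undefined"), n_uris),
    misplaced_classes_or_properties =
      list(errs(kinds = c("misplaced_class", "misplaced_property")),
           n_classes + n_props),
    misused_datatype_or_object_property =
      list(errs(kinds = c("misused_datatype_property",
                          "misused_object_property")), n_props),
    deprecated_classes_or_properties =
      list(errs(kinds = c("deprecated_class", "deprecated_property")),
           n_classes + n_props)
  )
  rows <- purrr::imap(sets, function(x, id) {
    uris <- x[[1]]; denom <- x[[2]]
    n <- length(uris)
    affected <- sum(triples_mentioning(doc, uris))
    tibble::tibble(
      metric_id = id, n_errors = n, denominator = denom,
      proportion = if (denom == 0) 0 else n / denom,
      value = sprintf("%d/%d", n, denom),
      affected_triples = affected, total_triples = n_triples,
      affected_pct = if (n_triples == 0) 0 else affected / n_triples,
      cell = format_cell(n, denom),
      error_uris = list(uris))
  })
  out <- dplyr::bind_rows(rows)
  out$metric_id <- factor(out$metric_id, levels = METRIC_IDS)
  out <- out[order(out$metric_id), ]
  out$metric_id <- as.character(out$metric_id)
  out
}
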