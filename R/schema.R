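#' Define the clinical feature schema of a case-report dataset
#'
#' A feature schema fixes the ordered list of clinical features (gender, age
#' group, primary suspect drug, ...), the admissible term vocabulary of each
#' feature, and which feature/term pair defines the binary endpoint (for
#' example the term \code{"death"} in the feature \code{"outcomes"}).
#'
#' @param features character vector of unique feature names, in render order.
#' @param vocab named list mapping each feature name to its character vector
#'   of admissible terms.
#' @param endpoint_feature name of the feature whose term defines the
#'   endpoint; must be one of \code{features}.
#' @param endpoint_term the term whose presence in \code{endpoint_feature}
#'   makes a report endpoint-positive; must be in that feature's vocabulary.
#' @param multi_valued character vector of feature names that may carry more
#'   than one term per report (e.g. \code{"adverse events"}).
#'
#' @return An object of class \code{feature_schema}.
#' @examples
#' sch <- feature_schema(
#'   features = c("gender", "outcomes"),
#'   vocab = list(gender = c("female", "male"),
#'                outcomes = c("death", "recovered")),
#'   endpoint_feature = "outcomes", endpoint_term = "death")
#' print(sch)
#' @export
feature_schema <- function(features, vocab, endpoint_feature, endpoint_term,
                           multi_valued = character()) {
  features <- as.character(features)
  if (anyDuplicated(features)) stopf("feature names must be unique")
  if (!is.list(vocab) || !all(features %in% names(vocab)))
    stopf("`vocab` must be a named list covering every feature")
  vocab <- lapply(vocab[features], as.character)
  if (!endpoint_feature %in% features)
    stopf("endpoint feature '%s' is not in the schema", endpoint_feature)
  if (!endpoint_term %in% vocab[[endpoint_feature]])
    stopf("endpoint term '%s' is not in the vocabulary of '%s'",
          endpoint_term, endpoint_feature)
  if (!all(multi_valued %in% features))
    stopf("multi_valued names must be schema features")
  structure(list(features = features, vocab = vocab,
                 endpoint_feature = endpoint_feature,
                 endpoint_term = endpoint_term,
                 multi_valued = as.character(multi_valued)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema:", length(x$features), "clinical features\n")
  for (f in x$features) {
    tag <- if (f == x$endpoint_feature) " [endpoint]" else ""
    mv <- if (f %in% x$multi_valued) " (multi-valued)" else ""
    cat(sprintf("  %s%s%s: %s\n", f, mv, tag,
                paste(x$vocab[[f]], collapse = ", ")))
  }
  cat(sprintf("Endpoint: '%s' in '%s'\n", x$endpoint_term, x$endpoint_feature))
  invisible(x)
}

#' Construct a single case report
#'
#' A case report maps each schema feature to a (possibly empty) set of terms;
#' an empty set means the feature is missing for that report.
#'
#' @param report_id opaque report identifier.
#' @param values named list, feature name -> character vector of terms.
#' @return An object of class \code{case_report}.
#' @export
case_report <- function(report_id, values) {
  structure(list(report_id = as.character(report_id),
                 values = lapply(values, as.character)),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("Case report", x$report_id, "\n")
  for (f in names(x$values)) {
    v <- x$values[[f]]
    cat(sprintf("  %s: %s\n", f,
                if (length(v) == 0) "<missing>" else paste(v, collapse = " | ")))
  }
  invisible(x)
}

report_ids <- function(reports) {
  vapply(reports, function(r) r$report_id, character(1))
}

# validate a list of case reports against a schema; duplicate ids and terms
# outside the vocabulary are hard errors (the invariant holds only after
# preprocessing, so `check_vocab` is opt-in)
validate_reports <- function(reports, schema, check_vocab = FALSE) {
  ids <- report_ids(reports)
  if (anyDuplicated(ids))
    stopf("duplicate report ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (r in reports) {
    extra <- setdiff(names(r$values), schema$features)
    if (length(extra))
      stopf("report %s has unknown features: %s", r$report_id,
            paste(extra, collapse = ", "))
    if (check_vocab) {
      for (f in names(r$values)) {
        bad <- setdiff(r$values[[f]], schema$vocab[[f]])
        if (length(bad))
          stopf("report %s: term(s) %s not in vocabulary of '%s'",
                r$report_id, paste(bad, collapse = ", "), f)
      }
    }
  }
  invisible(TRUE)
}

# Precompute, per feature, a reports x terms presence matrix plus a
# non-missing indicator. This is the workhorse behind the do/not-do
# partitions and the contingency tables.
feature_presence <- function(reports, schema) {
  n <- length(reports)
  out <- list()
  for (f in setdiff(schema$features, character(0))) {
    terms <- schema$vocab[[f]]
    pres <- matrix(FALSE, nrow = n, ncol = length(terms),
                   dimnames = list(NULL, terms))
    nonmissing <- logical(n)
    for (i in seq_len(n)) {
      v <- reports[[i]]$values[[f]]
      if (!is.null(v) && length(v) > 0) {
        nonmissing[i] <- TRUE
        pres[i, match(intersect(v, terms), terms)] <- TRUE
      }
    }
    out[[f]] <- list(presence = pres, nonmissing = nonmissing)
  }
  attr(out, "report_ids") <- report_ids(reports)
  out
}
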