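#' Read case reports from CSV or JSON-lines
#'
#' One row (CSV) or one JSON object per line (JSONL) per report. Multi-valued
#' cells in CSV use a delimiter (default \code{"|"}); JSONL uses native
#' arrays. Raw strings are passed through verbatim: normalisation of missing
#' tokens happens later in \code{\link{normalize_reports}}, so an empty CSV
#' cell loads as the empty string.
#'
#' @param path file to read.
#' @param schema a \code{\link{feature_schema}}.
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @param delim delimiter for multi-valued CSV cells.
#' @param id_column name of the report-id column/key.
#' @return list of \code{\link{case_report}} objects.
#' @export
read_case_reports <- function(path, schema, format = c("csv", "jsonl"),
                              delim = "|", id_column = "report_id") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  reports <- if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
    if (!id_column %in% names(df)) stopf("missing id column '%s'", id_column)
    missing_feats <- setdiff(schema$features, names(df))
    if (length(missing_feats))
      stopf("columns missing for features: %s",
            paste(missing_feats, collapse = ", "))
    extra <- setdiff(names(df), c(id_column, schema$features))
    if (length(extra))
      warnf("ignoring unknown columns: %s", paste(extra, collapse = ", "))
    lapply(seq_len(nrow(df)), function(i) {
      vals <- lapply(schema$features, function(f) {
        cell <- df[[f]][i]
        if (f %in% schema$multi_valued && nzchar(cell))
          strsplit(cell, delim, fixed = TRUE)[[1]]
        else cell
      })
      names(vals) <- schema$features
      case_report(df[[id_column]][i], vals)
    })
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e)
                        stopf("unreadable JSONL at line %d: %s", i,
                              conditionMessage(e)))
      if (is.null(obj[[id_column]])) stopf("line %d lacks '%s'", i, id_column)
      extra <- setdiff(names(obj), c(id_column, schema$features))
      if (length(extra))
        warnf("line %d: ignoring unknown keys: %s", i,
              paste(extra, collapse = ", "))
      vals <- lapply(schema$features, function(f) {
        v <- obj[[f]]
        if (is.null(v)) "" else as.character(v)
      })
      names(vals) <- schema$features
      case_report(obj[[id_column]], vals)
    })
  }
  validate_reports(reports, schema)
  reports
}

#' Write case reports to CSV or JSON-lines
#'
#' Inverse of \code{\link{read_case_reports}}; writing then reading returns
#' the same reports field-by-field (missing features round-trip as empty
#' sets once normalised).
#'
#' @inheritParams read_case_reports
#' @param reports list of \code{\link{case_report}} objects.
#' @export
write_case_reports <- function(reports, path, schema,
                               format = c("csv", "jsonl"), delim = "|") {
  format <- match.arg(format)
  if (format == "csv") {
    cols <- c(list(report_id = report_ids(reports)),
              stats::setNames(lapply(schema$features, function(f) {
                vapply(reports, function(r)
                  paste(r$values[[f]] %||% character(), collapse = delim),
                  character(1))
              }), schema$features))
    utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                     row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (r in reports) {
      obj <- c(list(report_id = jsonlite::unbox(r$report_id)),
               lapply(r$values, function(v) as.character(v)))
      writeLines(jsonlite::toJSON(obj, null = "null"), con)
    }
  }
  invisible(path)
}

#' Write enriched causal terms to TSV or JSON
#'
#' Columns mirror the enrichment report: clinical feature, term, z-score,
#' raw and adjusted p, average do / not-do probabilities, group sizes.
#'
#' @param terms a \code{causal_terms} object or the underlying data frame.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_results <- function(terms, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(terms)[, causal_term_columns(), drop = FALSE]
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read back a causal-term table written by \code{\link{write_results}}
#' @inheritParams write_results
#' @return data frame with the causal-term columns.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (format == "tsv") {
    utils::read.delim(path, colClasses = c(feature = "character",
                                           term = "character"),
                      check.names = FALSE, fileEncoding = "UTF-8")
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
  if (nrow(df) == 0)
    df <- empty_causal_terms()
  df[, causal_term_columns(), drop = FALSE]
}

causal_term_columns <- function() {
  c("feature", "term", "z", "p_raw", "p_adj",
    "mean_do", "mean_notdo", "n1", "n2")
}

empty_causal_terms <- function() {
  data.frame(feature = character(), term = character(), z = numeric(),
              p_raw = numeric(), p_adj = numeric(), mean_do = numeric(),
              mean_notdo = numeric(), n1 = integer(), n2 = integer(),
              stringsAsFactors = FALSE)
}
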