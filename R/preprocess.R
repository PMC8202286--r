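#' Preprocessing configuration
#'
#' Collects the cleaning rules applied to raw case reports: which tokens
#' count as missing, the dose dichotomy threshold (milligrams), the age bin
#' edges, the stratified split ratios and the shuffling seed.
#'
#' @param missing_tokens strings treated as missing values (case-insensitive).
#' @param dose_threshold_mg dose cut point in mg; doses strictly above it are
#'   "larger than 100 mg".
#' @param age_bins increasing interior bin edges in years.
#' @param split_ratios train/dev/test fractions summing to 1.
#' @param seed integer seed for the split shuffle.
#' @param dose_units named multipliers converting a unit to milligrams;
#'   unknown units map the dose to missing.
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(missing_tokens = c("unk", "unknown", "()", "", "na", "n/a"),
                              dose_threshold_mg = 100,
                              age_bins = c(18, 40, 65),
                              split_ratios = c(train = 0.64, dev = 0.16, test = 0.20),
                              seed = 1L,
                              dose_units = c(mg = 1, g = 1000, ug = 0.001)) {
  if (length(split_ratios) != 3 || any(split_ratios < 0))
    stopf("split_ratios must be three non-negative fractions")
  if (abs(sum(split_ratios) - 1) > 1e-9)
    stopf("split ratios must sum to 1 (got %.10f)", sum(split_ratios))
  if (is.unsorted(age_bins, strictly = TRUE))
    stopf("age bins must be strictly increasing")
  structure(list(missing_tokens = tolower(missing_tokens),
                 dose_threshold_mg = dose_threshold_mg,
                 age_bins = age_bins,
                 split_ratios = stats::setNames(as.numeric(split_ratios),
                                                c("train", "dev", "test")),
                 seed = as.integer(seed),
                 dose_units = dose_units),
            class = "preprocess_config")
}

#' Normalise missing-value tokens
#'
#' Tokens such as \code{"UNK"}, \code{"UNKNOWN"} and \code{"()"} (and empty
#' or whitespace-only strings) are collapsed to \code{NA}, the package's
#' missing marker; anything else is returned trimmed.
#'
#' @param raw character vector of raw cell values.
#' @param missing_tokens lowercase tokens treated as missing.
#' @return character vector with \code{NA} for missing entries.
#' @examples
#' normalize_missing(c("UNKNOWN", "()", " Tramadol "))
#' @export
normalize_missing <- function(raw,
                              missing_tokens = preprocess_config()$missing_tokens) {
  trimmed <- trimws(as.character(raw))
  out <- trimmed
  out[!nzchar(trimmed) | tolower(trimmed) %in% missing_tokens] <- NA_character_
  out
}

#' Apply missing-token normalisation to every value of every report
#'
#' After normalisation a feature with no informative terms carries the empty
#' set (the missing state the do/not-do partition relies on).
#'
#' @param reports list of \code{\link{case_report}}s.
#' @param config a \code{\link{preprocess_config}}.
#' @return the reports with cleaned value sets.
#' @export
normalize_reports <- function(reports, config = preprocess_config()) {
  lapply(reports, function(r) {
    r$values <- lapply(r$values, function(v) {
      v <- normalize_missing(v, config$missing_tokens)
      v[!is.na(v)]
    })
    r
  })
}

#' Dichotomise a dose in milligrams
#'
#' @param dose_mg numeric dose already unified to mg; must be non-negative.
#' @param threshold cut point; strictly above maps to the high class, so a
#'   dose of exactly 100 mg falls in "less than 100 mg".
#' @return \code{"larger than 100 mg"} or \code{"less than 100 mg"} (the
#'   class labels keep the threshold wording regardless of \code{threshold}).
#' @export
categorize_dose <- function(dose_mg, threshold = 100) {
  dose_mg <- as.numeric(dose_mg)
  if (any(!is.na(dose_mg) & dose_mg < 0)) stopf("negative dose")
  ifelse(is.na(dose_mg), NA_character_,
         ifelse(dose_mg > threshold, "larger than 100 mg", "less than 100 mg"))
}

#' Convert a dose value/unit pair to milligrams
#'
#' @param value numeric dose values.
#' @param unit character units; unknown units yield \code{NA} (missing dose).
#' @param units named multipliers to mg.
#' @return numeric mg values.
#' @export
convert_dose_mg <- function(value, unit, units = preprocess_config()$dose_units) {
  mult <- units[tolower(trimws(unit))]
  as.numeric(value) * as.numeric(mult)
}

#' Bin a patient age in years into four groups
#'
#' Bins are \code{[0,18)}, \code{[18,40)}, \code{[40,65)} and \code{[65,Inf)};
#' an age of exactly 65 falls in the oldest group.
#'
#' @param age_years numeric ages; must be non-negative.
#' @param bins interior bin edges.
#' @return factor-free character vector with levels
#'   \code{"<18"}, \code{"18-39"}, \code{"40-64"}, \code{"65+"}.
#' @export
categorize_age <- function(age_years, bins = c(18, 40, 65)) {
  age_years <- as.numeric(age_years)
  if (any(!is.na(age_years) & age_years < 0)) stopf("negative age")
  labels <- c("<18", "18-39", "40-64", "65+")
  idx <- findInterval(age_years, bins) + 1L
  ifelse(is.na(age_years), NA_character_, labels[idx])
}

#' Label the endpoint status of case reports
#'
#' A report is positive when the endpoint term is present in the endpoint
#' feature, excluded when the endpoint feature is missing (no outcome
#' information to learn from), negative otherwise.
#'
#' @param reports a single \code{\link{case_report}} or a list of them.
#' @param schema a \code{\link{feature_schema}}.
#' @return character vector of \code{"positive"}, \code{"negative"},
#'   \code{"excluded"}.
#' @export
label_endpoint <- function(reports, schema) {
  if (inherits(reports, "case_report")) reports <- list(reports)
  ef <- schema$endpoint_feature
  vapply(reports, function(r) {
    v <- r$values[[ef]]
    if (is.null(v) || length(v) == 0) "excluded"
    else if (schema$endpoint_term %in% v) "positive"
    else "negative"
  }, character(1))
}

# canonical slot order of the sentence template
.template_slots <- c("gender", "age", "primary suspect drug", "dose",
                     "indication", "adverse events", "outcomes")

render_slot <- function(values, placeholder = "unknown") {
  if (is.null(values) || length(values) == 0) placeholder
  else paste(values, collapse = " and ")
}

#' Render a case report as a template sentence
#'
#' The sentence follows a fixed clinical template: "Patient (gender and age)
#' takes a primary suspect drug (dose) to treat which disease and cause some
#' adverse events, leading to outcomes." Multi-valued slots are joined with
#' "and"; missing slots render as "unknown". To keep the endpoint label out
#' of the text, the endpoint term is excised from its slot when the endpoint
#' lives in "adverse events", and the whole outcomes clause is dropped when
#' the endpoint lives in "outcomes"; for any other endpoint feature its slot
#' is dropped entirely.
#'
#' @param report a \code{\link{case_report}} labeled positive or negative.
#' @param schema a \code{\link{feature_schema}}.
#' @return character sentence.
#' @export
generate_sentence <- function(report, schema) {
  vals <- report$values
  ef <- schema$endpoint_feature
  if (identical(ef, "adverse events")) {
    vals[[ef]] <- setdiff(vals[[ef]], schema$endpoint_term)
  }
  canonical <- all(.template_slots %in% schema$features) ||
    all(schema$features %in% .template_slots)
  if (canonical && !ef %in% c("adverse events", "outcomes"))
    vals[[ef]] <- character(0)  # blank the slot so the label cannot leak
  if (canonical) {
    parts <- sprintf("Patient %s %s takes %s %s to treat %s and cause %s",
                     render_slot(vals[["gender"]]),
                     render_slot(vals[["age"]]),
                     render_slot(vals[["primary suspect drug"]]),
                     render_slot(vals[["dose"]]),
                     render_slot(vals[["indication"]]),
                     render_slot(vals[["adverse events"]]))
    if (!identical(ef, "outcomes") && "outcomes" %in% schema$features)
      parts <- paste0(parts, ", leading to ", render_slot(vals[["outcomes"]]))
    parts
  } else {
    feats <- setdiff(schema$features, ef)
    clauses <- vapply(feats, function(f)
      paste(f, render_slot(vals[[f]])), character(1))
    paste("Patient with", paste(clauses, collapse = ", "))
  }
}

#' Render all labeled reports into sentence records
#'
#' Excluded reports (missing endpoint feature) are dropped; the remainder
#' become one row each with the rendered text and the 0/1 endpoint label.
#'
#' @inheritParams label_endpoint
#' @return data frame with columns \code{report_id}, \code{text},
#'   \code{label}.
#' @export
generate_sentences <- function(reports, schema) {
  status <- label_endpoint(reports, schema)
  keep <- status != "excluded"
  kept <- reports[keep]
  data.frame(report_id = report_ids(kept),
             text = vapply(kept, generate_sentence, character(1),
                           schema = schema),
             label = as.integer(status[keep] == "positive"),
             stringsAsFactors = FALSE)
}

# floor allocation with largest-remainder correction; remainders broken
# train-first so every class's total is conserved exactly
allocate_counts <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    order_idx <- order(-frac, seq_along(ratios))
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Stratified train/dev/test split of sentence records
#'
#' Records are shuffled per class under the seed, then allocated to splits
#' with floor counts plus largest-remainder correction (remainders going to
#' train first), so class totals are conserved exactly and each split's
#' positive fraction tracks the global one.
#'
#' @param records sentence data frame from \code{\link{generate_sentences}}.
#' @param ratios named train/dev/test fractions summing to 1.
#' @param seed integer shuffle seed.
#' @return object of class \code{split_dataset}: list with \code{train},
#'   \code{dev}, \code{test} data frames.
#' @export
stratified_split <- function(records,
                             ratios = c(train = 0.64, dev = 0.16, test = 0.20),
                             seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stopf("split ratios must sum to 1")
  classes <- unique(records$label)
  if (any(ratios <= 0) && nrow(records) > 0)
    stopf("zero split ratio with non-empty classes")
  if (!all(c(0, 1) %in% classes))
    stopf("need at least one positive and one negative record")
  parts <- list(train = list(), dev = list(), test = list())
  with_seed(seed, {
    for (cl in sort(classes)) {
      sub <- records[records$label == cl, , drop = FALSE]
      sub <- sub[sample.int(nrow(sub)), , drop = FALSE]
      sizes <- allocate_counts(nrow(sub), ratios)
      idx <- c(0, cumsum(sizes))
      for (s in 1:3) {
        take <- if (sizes[s] > 0) sub[(idx[s] + 1):idx[s + 1], , drop = FALSE]
                else sub[0, , drop = FALSE]
        parts[[s]][[as.character(cl)]] <- take
      }
    }
  })
  out <- lapply(parts, function(p) {
    df <- do.call(rbind, p)
    rownames(df) <- NULL
    df
  })
  structure(out, class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("Stratified split:\n")
  for (s in names(x)) {
    n <- nrow(x[[s]])
    pos <- sum(x[[s]]$label == 1)
    cat(sprintf("  %-5s n=%d (%d positive, %d negative)\n",
                s, n, pos, n - pos))
  }
  invisible(x)
}

#' Summarise a sentence corpus
#'
#' Reports the positive/negative counts, their ratio rounded to two
#' decimals, and the mean and standard deviation of the whitespace-token
#' sequence length of the rendered sentences.
#'
#' @param records sentence data frame.
#' @return list with \code{n_pos}, \code{n_neg}, \code{pos_neg_ratio},
#'   \code{seq_len_mean}, \code{seq_len_sd}.
#' @export
dataset_summary <- function(records) {
  if (nrow(records) == 0) stopf("empty record set")
  n_pos <- sum(records$label == 1)
  n_neg <- sum(records$label == 0)
  lens <- lengths(strsplit(records$text, "\\s+"))
  list(n_pos = n_pos, n_neg = n_neg,
       pos_neg_ratio = if (n_neg == 0) NA_real_ else round(n_pos / n_neg, 2),
       seq_len_mean = mean(lens), seq_len_sd = stats::sd(lens))
}

#' Top corpus terms by tf-idf
#'
#' Term frequency times smoothed inverse document frequency
#' (\code{log((1+N)/(1+df)) + 1}), L2-normalised per document; a term's
#' corpus score is its normalised weight averaged over the documents that
#' contain it, so salient rare terms surface at the top. Ties are broken
#' alphabetically.
#'
#' @param records sentence data frame (or character vector of documents).
#' @param k number of top terms to return; capped at the vocabulary size.
#' @return data frame with columns \code{term}, \code{tfidf}, ranked.
#' @export
tfidf_top_terms <- function(records, k = 10) {
  if (!is_count(k)) stopf("k must be a positive integer")
  docs <- if (is.character(records)) records else records$text
  if (length(docs) == 0) stopf("empty corpus")
  toks <- lapply(docs, tokenize_text)
  vocab <- sort(unique(unlist(toks)))
  n_docs <- length(docs)
  tf <- matrix(0, n_docs, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n_docs)) {
    tab <- table(toks[[i]])
    tf[i, names(tab)] <- as.numeric(tab)
  }
  df_count <- colSums(tf > 0)
  idf <- log((1 + n_docs) / (1 + df_count)) + 1
  w <- sweep(tf, 2, idf, `*`)
  norms <- sqrt(rowSums(w^2))
  norms[norms == 0] <- 1
  w <- w / norms
  score <- colSums(w) / pmax(df_count, 1)
  ord <- order(-score, vocab)
  top <- ord[seq_len(min(k, length(vocab)))]
  data.frame(term = vocab[top], tfidf = unname(score[top]),
             stringsAsFactors = FALSE)
}
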