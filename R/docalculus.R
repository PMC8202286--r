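#' Partition predicted probabilities into do / not-do strata for a term
#'
#' Reports containing the term form the "do" stratum L1; reports whose
#' feature is observed but lacks the term form the "not do" stratum L2;
#' reports with a missing feature enter neither.
#'
#' @param reports list of \code{\link{case_report}}s.
#' @param probs named probability vector from
#'   \code{\link{predict.endpoint_classifier}}, keyed by report id.
#' @param feature,term the clinical feature and term to intervene on; the
#'   feature must not be the endpoint feature.
#' @param schema a \code{\link{feature_schema}}.
#' @return object of class \code{term_partition} with elements \code{term},
#'   \code{feature}, \code{L1}, \code{L2} (probability vectors) and
#'   \code{ids1}, \code{ids2}.
#' @export
partition_by_term <- function(reports, probs, feature, term, schema) {
  if (identical(feature, schema$endpoint_feature))
    stopf("cannot intervene on the endpoint feature")
  if (!term %in% schema$vocab[[feature]])
    stopf("term '%s' is not in the vocabulary of '%s'", term, feature)
  ids <- report_ids(reports)
  keep <- ids %in% names(probs)
  reports <- reports[keep]; ids <- ids[keep]
  has_term <- logical(length(reports))
  nonmissing <- logical(length(reports))
  for (i in seq_along(reports)) {
    v <- reports[[i]]$values[[feature]]
    nonmissing[i] <- !is.null(v) && length(v) > 0
    has_term[i] <- nonmissing[i] && term %in% v
  }
  ids1 <- ids[has_term]
  ids2 <- ids[nonmissing & !has_term]
  structure(list(term = term, feature = feature,
                 L1 = unname(probs[ids1]), L2 = unname(probs[ids2]),
                 ids1 = ids1, ids2 = ids2),
            class = "term_partition")
}

#' One-tailed two-sample z-test on probability strata
#'
#' Tests whether the mean predicted endpoint probability of the do stratum
#' exceeds that of the not-do stratum. The statistic is the unpooled
#' (Welch-form) two-sample z,
#' \deqn{z = (\bar{L1} - \bar{L2}) / \sqrt{s_1^2/n_1 + s_2^2/n_2},}
#' with unbiased sample variances, and the p-value the upper tail of the
#' standard normal. A pooled-variance variant is available for sensitivity
#' analysis. Degenerate strata (both variances zero) yield z = 0, p = 0.5
#' when the means agree and a signed infinite z sentinel (p of 0 or 1)
#' when they differ.
#'
#' @param L1,L2 numeric probability vectors (do / not-do).
#' @param pooled use the pooled-variance form instead of Welch.
#' @return list with \code{z}, \code{p}, \code{mean_do}, \code{mean_notdo},
#'   \code{n1}, \code{n2}.
#' @examples
#' ztest_one_tailed(c(0.9, 0.8, 0.7), c(0.3, 0.2, 0.1))
#' @export
ztest_one_tailed <- function(L1, L2, pooled = FALSE) {
  n1 <- length(L1); n2 <- length(L2)
  if (n1 < 2 || n2 < 2) stopf("each stratum needs at least two values")
  m1 <- mean(L1); m2 <- mean(L2)
  v1 <- stats::var(L1); v2 <- stats::var(L2)
  se <- if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    sqrt(sp2 * (1 / n1 + 1 / n2))
  } else sqrt(v1 / n1 + v2 / n2)
  if (se == 0) {
    z <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    z <- (m1 - m2) / se
  }
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE),
       mean_do = m1, mean_notdo = m2, n1 = n1, n2 = n2)
}

#' Adjust p-values for multiplicity
#'
#' Bonferroni (default, conservative) or Benjamini-Hochberg step-up; the
#' family is every term tested in the run.
#'
#' @param p numeric p-values in [0, 1].
#' @param method \code{"bonferroni"} or \code{"bh"}.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Enrich causal terms by interventional probing of the classifier
#'
#' Iterates every term of every non-endpoint clinical feature, partitions
#' the predicted probabilities into do / not-do strata, applies the
#' one-tailed z-test, adjusts the p-values over all tested terms, and
#' returns the terms enriched at \code{p_adj < alpha}, sorted by z
#' descending (ties alphabetical). Terms whose strata fall below
#' \code{min_group_size} are skipped (recorded in the \code{skipped}
#' attribute). The per-feature top term among the enriched set — the root
#' cause of each clinical feature category — is in the
#' \code{root_causes} attribute.
#'
#' @inheritParams partition_by_term
#' @param alpha significance level on the adjusted p-value.
#' @param min_group_size smallest stratum size admitted to the z-test
#'   (normal-approximation heuristic).
#' @param adjust multiplicity correction, see \code{\link{adjust_pvalues}}.
#' @param pooled use the pooled-variance z.
#' @param features features to probe; defaults to all non-endpoint features.
#' @return object of class \code{causal_terms}: a data frame with columns
#'   \code{feature}, \code{term}, \code{z}, \code{p_raw}, \code{p_adj},
#'   \code{mean_do}, \code{mean_notdo}, \code{n1}, \code{n2}, with
#'   attributes \code{all_tested}, \code{root_causes}, \code{skipped},
#'   \code{alpha}, \code{adjust}.
#' @export
infer_causes <- function(reports, probs, schema, alpha = 0.05,
                         min_group_size = 30, adjust = c("bonferroni", "bh"),
                         pooled = FALSE, features = NULL) {
  adjust <- match.arg(adjust)
  features <- features %||% setdiff(schema$features, schema$endpoint_feature)
  ids <- report_ids(reports)
  keep <- ids %in% names(probs)
  reports <- reports[keep]
  pres <- feature_presence(reports, schema)
  pvec <- unname(probs[report_ids(reports)])
  rows <- list()
  skipped <- list()
  for (f in features) {
    fp <- pres[[f]]
    for (term in schema$vocab[[f]]) {
      in_do <- fp$presence[, term]
      in_not <- fp$nonmissing & !in_do
      n1 <- sum(in_do); n2 <- sum(in_not)
      if (n1 < min_group_size || n2 < min_group_size) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(feature = f, term = term, n1 = n1, n2 = n2,
                     reason = "stratum below min_group_size")
        next
      }
      zt <- ztest_one_tailed(pvec[in_do], pvec[in_not], pooled = pooled)
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, term = term, z = zt$z, p_raw = zt$p,
                   mean_do = zt$mean_do, mean_notdo = zt$mean_notdo,
                   n1 = n1, n2 = n2, stringsAsFactors = FALSE)
    }
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL
  if (length(rows) == 0) {
    warnf("no testable terms (all strata below min_group_size)")
    res <- empty_causal_terms()
    return(structure(res, all_tested = res, root_causes = res,
                     skipped = skipped, alpha = alpha, adjust = adjust,
                     class = c("causal_terms", "data.frame")))
  }
  tested <- do.call(rbind, rows)
  tested$p_adj <- adjust_pvalues(tested$p_raw, adjust)
  tested <- tested[, causal_term_columns()]
  enriched <- tested[tested$p_adj < alpha, , drop = FALSE]
  enriched <- enriched[order(-enriched$z, enriched$term), , drop = FALSE]
  rownames(enriched) <- NULL
  roots <- do.call(rbind, lapply(split(enriched, enriched$feature),
                                 function(d) d[which.max(d$z), , drop = FALSE]))
  if (!is.null(roots)) {
    roots <- roots[order(-roots$z), , drop = FALSE]
    rownames(roots) <- NULL
  } else roots <- empty_causal_terms()
  structure(enriched, all_tested = tested, root_causes = roots,
            skipped = skipped, alpha = alpha, adjust = adjust,
            class = c("causal_terms", "data.frame"))
}

#' @export
print.causal_terms <- function(x, digits = 3, ...) {
  cat(sprintf("Enriched causal terms: %d of %d tested (alpha = %g, %s)\n",
              nrow(x), nrow(attr(x, "all_tested")), attr(x, "alpha"),
              attr(x, "adjust")))
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$z <- signif(df$z, digits)
    df$p_adj <- signif(df$p_adj, digits)
    df$p_raw <- signif(df$p_raw, digits)
    df$mean_do <- round(df$mean_do, 2)
    df$mean_notdo <- round(df$mean_notdo, 2)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.causal_terms <- function(object, ...) {
  cat("Root causes (top z per clinical feature):\n")
  roots <- attr(object, "root_causes")
  if (nrow(roots)) print.data.frame(roots, row.names = FALSE, digits = 4)
  sk <- attr(object, "skipped")
  if (!is.null(sk))
    cat(sprintf("%d term(s) skipped for undersized strata\n", nrow(sk)))
  invisible(roots)
}
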