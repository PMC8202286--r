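#' Average percentage of common enriched terms across repeated runs
#'
#' For runs i = 1..T with enriched term sets S_i and common set
#' C = S_1 \eqn{\cap} ... \eqn{\cap} S_T, returns
#' \eqn{100 \cdot \frac{1}{T}\sum_i |C| / |S_i|}: the mean share of each
#' run's enriched terms that every run reproduced.
#'
#' @param runs list of character vectors of enriched terms (one per run);
#'   every run must be non-empty.
#' @return percentage in [0, 100].
#' @examples
#' average_pct_enriched(list(c("A","B","C"), c("A","B"), c("A","B","D")))
#' @export
average_pct_enriched <- function(runs) {
  if (length(runs) < 2) stopf("need at least two runs")
  if (any(lengths(runs) == 0)) stopf("empty run: percentage undefined")
  common <- Reduce(intersect, runs)
  100 * mean(length(common) / lengths(runs))
}

#' Percentage-of-overlapped-terms (POT) curve
#'
#' Runs are z-ranked term lists; for each prefix size k (1 up to the
#' shortest run), POT(k) is the size of the intersection of all runs' top-k
#' prefixes divided by k.
#'
#' @param runs list of ranked character vectors.
#' @return data frame with columns \code{k} and \code{pot}.
#' @examples
#' pot_curve(list(c("A","B","C","D"), c("A","C","B","D"), c("B","A","D","C")))
#' @export
pot_curve <- function(runs) {
  if (length(runs) < 2) stopf("need at least two runs")
  kmax <- min(lengths(runs))
  ks <- seq_len(kmax)
  pot <- vapply(ks, function(k) {
    length(Reduce(intersect, lapply(runs, utils::head, k))) / k
  }, numeric(1))
  data.frame(k = ks, pot = pot)
}

#' Seven-region Venn tally of three runs' enriched-term sets
#' @param runs list of exactly three character vectors.
#' @return named integer vector of the 7 region sizes
#'   (\code{"100"}, \code{"010"}, ..., \code{"111"}).
#' @export
venn_counts <- function(runs) {
  if (length(runs) != 3) stopf("venn_counts expects exactly three runs")
  u <- unique(unlist(runs))
  member <- vapply(runs, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1)
  code <- apply(member, 1, function(m) paste(as.integer(m), collapse = ""))
  regions <- c("100", "010", "001", "110", "101", "011", "111")
  out <- stats::setNames(integer(7), regions)
  tab <- table(code)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Repeat the train/predict/probe pipeline under different seeds
#'
#' Re-runs classifier training, probability prediction and causal-term
#' enrichment once per seed, holding data and every other parameter fixed,
#' and collects each run's z-ranked enriched term list (labelled
#' \code{"feature: term"}; z ties broken alphabetically so the ranking is
#' well defined).
#'
#' @param reports normalised case reports (the probing population).
#' @param train,dev sentence splits used to fit the classifier.
#' @param schema a \code{\link{feature_schema}}.
#' @param config a \code{\link{classifier_config}}; its seed is replaced by
#'   each element of \code{seeds} in turn.
#' @param seeds integer vector (at least two) of run seeds.
#' @param alpha,min_group_size,adjust passed to \code{\link{infer_causes}}.
#' @return object of class \code{run_collection}: list with \code{runs}
#'   (ranked term lists), \code{seeds} and \code{diagnostics} (per-run dev
#'   accuracy and enrichment count).
#' @export
repeat_runs <- function(reports, train, dev, schema, config, seeds,
                        alpha = 0.05, min_group_size = 30,
                        adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  if (length(seeds) < 2) stopf("need at least two seeds")
  sentences <- generate_sentences(reports, schema)
  runs <- vector("list", length(seeds))
  diags <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    res <- tryCatch({
      model <- fit_endpoint_classifier(train, dev, cfg)
      probs <- predict(model, sentences)
      terms <- infer_causes(reports, probs, schema, alpha = alpha,
                            min_group_size = min_group_size, adjust = adjust)
      list(model = model, terms = terms)
    }, error = function(e)
      stopf("run with seed %d failed: %s", seeds[i], conditionMessage(e)))
    ranked <- res$terms[order(-res$terms$z, res$terms$term), , drop = FALSE]
    runs[[i]] <- paste(ranked$feature, ranked$term, sep = ": ")
    diags[[i]] <- data.frame(seed = seeds[i],
                             dev_accuracy = res$model$dev_accuracy,
                             n_enriched = nrow(res$terms))
  }
  structure(list(runs = runs, seeds = seeds,
                 diagnostics = do.call(rbind, diags)),
            class = "run_collection")
}

#' @export
print.run_collection <- function(x, ...) {
  cat(sprintf("Run collection: %d repeated runs\n", length(x$runs)))
  print(x$diagnostics, row.names = FALSE)
  if (all(lengths(x$runs) > 0))
    cat(sprintf("Average %% of common enriched terms: %.1f%%\n",
                average_pct_enriched(x$runs)))
  invisible(x)
}
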