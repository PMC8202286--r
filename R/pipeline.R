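#' Run the full analysis pipeline
#'
#' Orchestrates preprocess -> split -> train -> predict -> causal probing ->
#' causal tree -> disproportionality (-> optional robustness) and writes
#' every stage artifact plus a manifest (configuration, seeds and file
#' checksums) to the output directory, so a run is reproducible from the
#' manifest alone.
#'
#' @param reports list of raw \code{\link{case_report}}s, or \code{NULL} to
#'   simulate from \code{sim} first.
#' @param schema a \code{\link{feature_schema}} (taken from \code{sim} when
#'   simulating).
#' @param out_dir output directory, created if needed.
#' @param sim optional \code{\link{sim_config}} used when \code{reports} is
#'   \code{NULL}.
#' @param pre a \code{\link{preprocess_config}}.
#' @param clf a \code{\link{classifier_config}}.
#' @param alpha,min_group_size,adjust causal-probe settings.
#' @param max_depth causal-tree depth cap.
#' @param robustness_seeds optional integer seeds; when at least two are
#'   given the robustness stage re-runs training per seed.
#' @return list with the manifest (also written as \code{manifest.json})
#'   and the in-memory stage results.
#' @export
run_pipeline <- function(reports = NULL, schema = NULL, out_dir,
                         sim = NULL, pre = preprocess_config(),
                         clf = classifier_config(), alpha = 0.05,
                         min_group_size = 30,
                         adjust = c("bonferroni", "bh"), max_depth = 3,
                         robustness_seeds = NULL) {
  adjust <- match.arg(adjust)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (is.null(reports)) {
    if (is.null(sim)) stopf("either reports or a sim config is required")
    schema <- sim$schema
    reports <- stage("simulate", generate_cases(sim))
    input_path <- file.path(out_dir, "cases.jsonl")
    write_case_reports(reports, input_path, schema, format = "jsonl")
  } else input_path <- NULL
  if (is.null(schema)) stopf("a schema is required")

  clean <- stage("preprocess", normalize_reports(reports, pre))
  sentences <- stage("preprocess", generate_sentences(clean, schema))
  p <- file.path(out_dir, "sentences.tsv")
  utils::write.table(sentences, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts["sentences"] <- p

  split <- stage("split", stratified_split(sentences, pre$split_ratios,
                                           seed = pre$seed))
  p <- file.path(out_dir, "split.json")
  jsonlite::write_json(lapply(split, function(d) d$report_id), p)
  artifacts["split"] <- p

  model <- stage("train", fit_endpoint_classifier(split$train, split$dev, clf))
  p <- file.path(out_dir, "training_trace.tsv")
  utils::write.table(model$trace, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts["trace"] <- p

  probs <- stage("predict", predict(model, sentences))
  p <- file.path(out_dir, "probabilities.tsv")
  utils::write.table(data.frame(report_id = names(probs), p = unname(probs)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts["probabilities"] <- p

  terms <- stage("infer", infer_causes(clean, probs, schema, alpha = alpha,
                                       min_group_size = min_group_size,
                                       adjust = adjust))
  p <- file.path(out_dir, "causal_terms.tsv")
  write_results(terms, p, format = "tsv")
  artifacts["causal_terms"] <- p

  tree <- stage("tree", build_causal_tree(clean, probs, schema,
                                          alpha = alpha,
                                          min_group_size = min_group_size,
                                          adjust = adjust,
                                          max_depth = max_depth))
  p <- file.path(out_dir, "causal_tree.json")
  export_tree(tree, p, format = "json")
  artifacts["tree"] <- p

  signals <- stage("dispro", score_signals(clean, schema))
  p <- file.path(out_dir, "signals.tsv")
  utils::write.table(signals, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts["signals"] <- p

  robust <- NULL
  if (length(robustness_seeds) >= 2) {
    robust <- stage("robustness",
                    repeat_runs(clean, split$train, split$dev, schema, clf,
                                seeds = robustness_seeds, alpha = alpha,
                                min_group_size = min_group_size,
                                adjust = adjust))
    p <- file.path(out_dir, "robustness.json")
    jsonlite::write_json(list(runs = robust$runs,
                              avg_pct_common = average_pct_enriched(robust$runs),
                              pot = pot_curve(robust$runs)),
                         p, auto_unbox = TRUE, digits = NA)
    artifacts["robustness"] <- p
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = list(preprocess = pre$seed, classifier = clf$seed,
                 simulate = if (!is.null(sim)) sim$seed else NULL,
                 robustness = robustness_seeds),
    settings = list(alpha = alpha, min_group_size = min_group_size,
                    adjust = adjust, max_depth = max_depth,
                    split_ratios = as.list(pre$split_ratios),
                    classifier = unclass(clf)),
    input = input_path,
    artifacts = as.list(artifacts),
    checksums = as.list(tools::md5sum(unname(c(input_path, artifacts)))),
    summary = list(n_reports = length(reports),
                   n_sentences = nrow(sentences),
                   dev_accuracy = model$dev_accuracy,
                   n_enriched = nrow(terms),
                   n_tree_nodes = nrow(tree_nodes(tree)),
                   n_signal_terms = sum(signals$is_signal)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(manifest = manifest, model = model, probs = probs, terms = terms,
       tree = tree, signals = signals, robustness = robust,
       split = split, sentences = sentences, reports = clean)
}
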