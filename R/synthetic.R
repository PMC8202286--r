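#' Configure the synthetic case-report generator
#'
#' Describes a population of FAERS-like case reports with known, planted
#' causal structure: per-feature term prevalences, per-feature missingness,
#' main effects on the endpoint log-odds, and optional second-level
#' interaction effects that are active only when both terms are present
#' (the ground truth for the causal tree). The endpoint is sampled from
#' \deqn{\mathrm{logit}\,P(\mathrm{positive}) = \mu + \sum_k \beta_k x_k +
#' \sum_{(p,c)} \gamma_{pc} x_p x_c} and written into the endpoint feature.
#'
#' @param n_reports number of reports to generate.
#' @param schema a \code{\link{feature_schema}}.
#' @param term_prevalences named list, feature -> named numeric of term
#'   prevalences in (0,1). Single-valued features sample one term from the
#'   normalised prevalences; multi-valued features include each term
#'   independently.
#' @param missing_rates named numeric, feature -> probability the feature is
#'   missing; defaults to 0.
#' @param effects named numeric of main-effect log-odds keyed by term
#'   (term names must be unambiguous across features).
#' @param interaction_effects data frame with columns \code{parent_term},
#'   \code{child_term}, \code{beta}; the extra log-odds applies only to
#'   reports carrying both terms.
#' @param intercept baseline log-odds of a positive endpoint.
#' @param seed integer generation seed.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_reports, schema, term_prevalences,
                       missing_rates = NULL, effects = numeric(),
                       interaction_effects = NULL, intercept = 0,
                       seed = 1L) {
  stopifnot(inherits(schema, "feature_schema"))
  feats <- setdiff(schema$features, schema$endpoint_feature)
  for (f in feats) {
    pv <- term_prevalences[[f]]
    if (is.null(pv) || !all(schema$vocab[[f]] %in% names(pv)))
      stopf("term_prevalences must cover every term of '%s'", f)
    if (any(pv <= 0 | pv >= 1)) stopf("prevalences must lie in (0, 1)")
  }
  missing_rates <- missing_rates %||%
    stats::setNames(rep(0, length(schema$features)), schema$features)
  term_feature <- term_feature_map(schema)
  for (tm in names(effects))
    if (!tm %in% names(term_feature))
      stopf("effect term '%s' not found (or ambiguous) in the schema", tm)
  if (!is.null(interaction_effects)) {
    stopifnot(all(c("parent_term", "child_term", "beta") %in%
                    colnames(interaction_effects)))
    for (tm in c(interaction_effects$parent_term,
                 interaction_effects$child_term))
      if (!tm %in% names(term_feature))
        stopf("interaction term '%s' not found in the schema", tm)
  }
  structure(list(n_reports = as.integer(n_reports), schema = schema,
                 term_prevalences = term_prevalences,
                 missing_rates = missing_rates,
                 effects = effects,
                 interaction_effects = interaction_effects,
                 intercept = intercept, seed = as.integer(seed)),
            class = "sim_config")
}

# map unambiguous term -> feature (terms appearing in several non-endpoint
# features are dropped from the map and cannot carry planted effects)
term_feature_map <- function(schema) {
  feats <- setdiff(schema$features, schema$endpoint_feature)
  all_terms <- unlist(lapply(feats, function(f) {
    stats::setNames(rep(f, length(schema$vocab[[f]])), schema$vocab[[f]])
  }))
  dup <- names(all_terms)[duplicated(names(all_terms))]
  all_terms[!names(all_terms) %in% dup]
}

#' Default FAERS-like simulation fixture
#'
#' Seven clinical features mirroring spontaneous-report data: gender, age
#' group, primary suspect drug, dose class, indication, adverse events
#' (multi-valued) and outcomes, with the endpoint "death" in outcomes. One
#' strong planted cause (the analgesic APAP, log-odds +2) and one
#' second-level effect (+1 extra log-odds for females, active only among
#' APAP reports); every feature keeps zero-effect terms as negative
#' controls. Intercept -1.5 puts the baseline positive rate near 0.33,
#' comparable to real spontaneous-report endpoint mixes.
#'
#' @param n_reports number of reports.
#' @param seed generation seed.
#' @param missing_rate shared missingness of the non-endpoint features.
#' @return a \code{\link{sim_config}}.
#' @export
default_sim_config <- function(n_reports = 5000, seed = 1L,
                               missing_rate = 0.1) {
  schema <- feature_schema(
    features = c("gender", "age", "primary suspect drug", "dose",
                 "indication", "adverse events", "outcomes"),
    vocab = list(
      gender = c("female", "male"),
      age = c("<18", "18-39", "40-64", "65+"),
      `primary suspect drug` = c("APAP", "tramadol", "ibuprofen",
                                 "naproxen", "morphine"),
      dose = c("less than 100 mg", "larger than 100 mg"),
      indication = c("pain", "fever", "arthritis", "headache", "depression"),
      `adverse events` = c("nausea", "vomiting", "dizziness", "rash",
                           "fatigue"),
      outcomes = c("death", "recovered", "hospitalization")),
    endpoint_feature = "outcomes", endpoint_term = "death",
    multi_valued = c("adverse events", "outcomes"))
  prev <- list(
    gender = c(female = 0.5, male = 0.5),
    age = c(`<18` = 0.1, `18-39` = 0.3, `40-64` = 0.35, `65+` = 0.25),
    `primary suspect drug` = c(APAP = 0.3, tramadol = 0.25, ibuprofen = 0.2,
                               naproxen = 0.15, morphine = 0.1),
    dose = c(`less than 100 mg` = 0.5, `larger than 100 mg` = 0.5),
    indication = c(pain = 0.4, fever = 0.2, arthritis = 0.15,
                   headache = 0.15, depression = 0.1),
    `adverse events` = c(nausea = 0.3, vomiting = 0.25, dizziness = 0.25,
                         rash = 0.2, fatigue = 0.3))
  mr <- stats::setNames(c(rep(missing_rate, 6), 0), schema$features)
  sim_config(n_reports, schema, prev, missing_rates = mr,
             effects = c(APAP = 2.0),
             interaction_effects = data.frame(parent_term = "APAP",
                                              child_term = "female",
                                              beta = 1.0,
                                              stringsAsFactors = FALSE),
             intercept = -1.5, seed = seed)
}

#' A null simulation fixture with no planted effects
#'
#' Same report structure as a calibration study: \code{n_features}
#' single-valued features whose term counts sum to \code{n_terms}, uniform
#' prevalences, zero effects and zero intercept, so the endpoint is an
#' independent coin flip.
#'
#' @param n_reports number of reports.
#' @param n_features number of non-endpoint features.
#' @param n_terms total number of non-endpoint terms.
#' @param seed generation seed.
#' @return a \code{\link{sim_config}}.
#' @export
null_sim_config <- function(n_reports = 3000, n_features = 5,
                            n_terms = 30, seed = 1L) {
  per <- rep(n_terms %/% n_features, n_features)
  extra <- n_terms - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  feats <- paste0("feature", seq_len(n_features))
  vocab <- stats::setNames(lapply(seq_len(n_features), function(j)
    sprintf("f%d_term%02d", j, seq_len(per[j]))), feats)
  vocab$outcome <- c("event", "none")
  schema <- feature_schema(c(feats, "outcome"), vocab,
                           endpoint_feature = "outcome",
                           endpoint_term = "event",
                           multi_valued = "outcome")
  prev <- stats::setNames(lapply(seq_len(n_features), function(j) {
    stats::setNames(rep(1 / per[j], per[j]), vocab[[feats[j]]])
  }), feats)
  sim_config(n_reports, schema, prev, intercept = 0, seed = seed)
}

#' Generate synthetic case reports with planted causal structure
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of \code{\link{case_report}}s; the endpoint feature of each
#'   report contains the endpoint term iff its sampled endpoint is
#'   positive.
#' @export
generate_cases <- function(config) {
  schema <- config$schema
  n <- config$n_reports
  feats <- setdiff(schema$features, schema$endpoint_feature)
  tf_map <- term_feature_map(schema)
  with_seed(config$seed, {
    values <- list()
    for (f in feats) {
      pv <- config$term_prevalences[[f]]
      terms <- schema$vocab[[f]]
      if (f %in% schema$multi_valued) {
        inc <- matrix(stats::runif(n * length(terms)) <
                        rep(pv[terms], each = n), n, length(terms))
        colnames(inc) <- terms
        values[[f]] <- lapply(seq_len(n), function(i) terms[inc[i, ]])
      } else {
        pick <- sample(terms, n, replace = TRUE, prob = pv[terms] / sum(pv[terms]))
        values[[f]] <- as.list(pick)
      }
      mr <- config$missing_rates[[f]] %||% 0
      if (mr > 0) {
        drop <- stats::runif(n) < mr
        values[[f]][drop] <- list(character(0))
      }
    }
    # endpoint log-odds from the planted model
    eta <- rep(config$intercept, n)
    has_term <- function(tm) {
      f <- tf_map[[tm]]
      vapply(values[[f]], function(v) tm %in% v, logical(1))
    }
    for (tm in names(config$effects))
      eta <- eta + config$effects[[tm]] * has_term(tm)
    ie <- config$interaction_effects
    if (!is.null(ie)) {
      for (i in seq_len(nrow(ie)))
        eta <- eta + ie$beta[i] *
          (has_term(ie$parent_term[i]) & has_term(ie$child_term[i]))
    }
    y <- stats::runif(n) < sigmoid(eta)
    # write the endpoint into the endpoint feature
    ef <- schema$endpoint_feature
    others <- setdiff(schema$vocab[[ef]], schema$endpoint_term)
    other_pick <- sample(others, n, replace = TRUE)
    ep_vals <- lapply(seq_len(n), function(i) {
      if (y[i]) schema$endpoint_term else other_pick[i]
    })
    mr <- config$missing_rates[[ef]] %||% 0
    if (mr > 0) {
      drop <- stats::runif(n) < mr
      ep_vals[drop] <- list(character(0))
    }
    lapply(seq_len(n), function(i) {
      vals <- lapply(feats, function(f) values[[f]][[i]])
      names(vals) <- feats
      vals[[ef]] <- ep_vals[[i]]
      case_report(sprintf("r%06d", i), vals[schema$features])
    })
  })
}

#' Ground truth of a simulation configuration
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{causal_terms} (data frame of feature/term/beta
#'   for nonzero main effects) and \code{conditional_pairs} (data frame of
#'   parent/child feature-term pairs with nonzero interaction effects).
#' @export
ground_truth <- function(config) {
  tf_map <- term_feature_map(config$schema)
  eff <- config$effects[config$effects != 0]
  ct <- if (length(eff)) {
    data.frame(feature = unname(tf_map[names(eff)]), term = names(eff),
               beta = unname(eff), stringsAsFactors = FALSE)
  } else {
    data.frame(feature = character(), term = character(), beta = numeric(),
               stringsAsFactors = FALSE)
  }
  ie <- config$interaction_effects
  cp <- if (!is.null(ie) && nrow(ie)) {
    data.frame(parent_feature = unname(tf_map[ie$parent_term]),
               parent_term = ie$parent_term,
               child_feature = unname(tf_map[ie$child_term]),
               child_term = ie$child_term,
               beta = ie$beta, stringsAsFactors = FALSE)
  } else {
    data.frame(parent_feature = character(), parent_term = character(),
               child_feature = character(), child_term = character(),
               beta = numeric(), stringsAsFactors = FALSE)
  }
  cp <- cp[cp$beta != 0, , drop = FALSE]
  list(causal_terms = ct, conditional_pairs = cp)
}
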