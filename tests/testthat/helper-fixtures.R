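# shared fixtures, all built in code at test time

tiny_schema <- function() {
  feature_schema(
    features = c("gender", "drug", "adverse events", "outcomes"),
    vocab = list(gender = c("female", "male"),
                 drug = c("APAP", "tramadol"),
                 `adverse events` = c("nausea", "acute liver failure", "rash"),
                 outcomes = c("death", "recovered", "hospitalization")),
    endpoint_feature = "outcomes", endpoint_term = "death",
    multi_valued = c("adverse events", "outcomes"))
}

tiny_reports <- function() {
  list(
    case_report("r1", list(gender = "female", drug = "APAP",
                           `adverse events` = c("nausea", "acute liver failure"),
                           outcomes = c("death", "hospitalization"))),
    case_report("r2", list(gender = "male", drug = "tramadol",
                           `adverse events` = "rash",
                           outcomes = "recovered")),
    case_report("r3", list(gender = character(0), drug = "APAP",
                           `adverse events` = character(0),
                           outcomes = "death")))
}

# corpus where one token ("toxin") perfectly predicts the label
separable_corpus <- function(n, seed = 1) {
  filler <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
              "theta", "kappa")
  pvprobe:::with_seed(seed, {
    lab <- rep(c(0L, 1L), length.out = n)[sample.int(n)]
    txt <- vapply(seq_len(n), function(i) {
      w <- sample(filler, 6, replace = TRUE)
      if (lab[i] == 1L) w[3] <- "toxin"
      paste(w, collapse = " ")
    }, character(1))
    data.frame(report_id = sprintf("s%04d", seq_len(n)), text = txt,
               label = lab, stringsAsFactors = FALSE)
  })
}

small_transformer_config <- function(seed = 1, total_steps = 150) {
  classifier_config("transformer", max_seq_len = 8, hidden_size = 16,
                    n_layers = 2, n_heads = 2, ff_size = 32,
                    batch_size = 16, total_steps = total_steps,
                    checkpoint_every = 25, seed = seed)
}

# simulate -> sentences -> split -> train -> predict -> probe, one seed
probe_run <- function(sim, kind = "token-logistic", seed = sim$seed,
                      alpha = 0.05, min_group_size = 30, clf = NULL) {
  reports <- generate_cases(sim)
  sentences <- generate_sentences(reports, sim$schema)
  split <- stratified_split(sentences, seed = seed)
  clf <- clf %||% classifier_config(kind, seed = seed)
  model <- fit_endpoint_classifier(split$train, split$dev, clf)
  probs <- predict(model, sentences)
  terms <- infer_causes(reports, probs, sim$schema, alpha = alpha,
                        min_group_size = min_group_size)
  list(reports = reports, sentences = sentences, split = split,
       model = model, probs = probs, terms = terms, schema = sim$schema)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Welch-z oracle: reuse t.test's Welch statistic (identical
# formula for the unpooled two-sample z) plus the upper-tail normal p
oracle_welch_z <- function(x, y) {
  z <- unname(stats::t.test(x, y)$statistic)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

# independent quadrature oracle for the gamma-Poisson posterior: integrate
# prior(lambda) * Poisson(a | lambda E) numerically, no conjugacy used
quad_oracle <- function(a, E, prior) {
  dens <- function(l) {
    d1 <- stats::dgamma(l, prior$alpha1, prior$beta1)
    if (prior$components == 2)
      prior$P * d1 + (1 - prior$P) * stats::dgamma(l, prior$alpha2, prior$beta2)
    else d1
  }
  unnorm <- function(l) dens(l) * stats::dpois(a, l * E)
  up <- max(20, 8 * (a + 1) / E)
  mode <- max(1e-3, a / E)
  # split at the likelihood peak so the quadrature resolves sharp posteriors
  intg <- function(f, lo, hi) {
    cuts <- sort(unique(pmin(pmax(c(lo, mode / 2, mode, 2 * mode, hi), lo), hi)))
    sum(vapply(seq_len(length(cuts) - 1), function(i)
      stats::integrate(f, cuts[i], cuts[i + 1], rel.tol = 1e-11,
                       subdivisions = 500L)$value, numeric(1)))
  }
  Z <- intg(unnorm, 0, up)
  elog <- intg(function(l) log(l) * unnorm(l), 1e-12, up) / Z
  cdf <- function(x) intg(unnorm, 0, x) / Z
  eb05 <- stats::uniroot(function(x) cdf(x) - 0.05, c(1e-8, up),
                         tol = 1e-9)$root
  list(ebgm = exp(elog), eb05 = eb05)
}

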