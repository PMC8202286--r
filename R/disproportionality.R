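#' Build the 2x2 term-by-endpoint contingency table
#'
#' Cell a counts reports carrying the term that are endpoint-positive, b
#' term and negative, c no-term (feature observed) and positive, d no-term
#' and negative. Reports with a missing feature or an excluded endpoint are
#' dropped, matching the cohort of the do / not-do partition so the methods
#' are compared on the same reports.
#'
#' @inheritParams partition_by_term
#' @return object of class \code{contingency_table}: list with \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{term}, \code{feature}.
#' @export
build_contingency <- function(reports, term, feature, schema) {
  if (!term %in% schema$vocab[[feature]])
    stopf("term '%s' is not in the vocabulary of '%s'", term, feature)
  status <- label_endpoint(reports, schema)
  keep <- status != "excluded"
  reports <- reports[keep]
  pos <- status[keep] == "positive"
  has <- logical(length(reports)); nonmissing <- logical(length(reports))
  for (i in seq_along(reports)) {
    v <- reports[[i]]$values[[feature]]
    nonmissing[i] <- !is.null(v) && length(v) > 0
    has[i] <- nonmissing[i] && term %in% v
  }
  structure(list(a = sum(has & pos), b = sum(has & !pos),
                 c = sum(nonmissing & !has & pos),
                 d = sum(nonmissing & !has & !pos),
                 term = term, feature = feature),
            class = "contingency_table")
}

contingency <- function(a, b, c, d, term = NA_character_,
                        feature = NA_character_) {
  structure(list(a = a, b = b, c = c, d = d, term = term, feature = feature),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table for '%s' (%s):\n", x$term, x$feature))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("term", "no term"),
                              c("positive", "negative")))
  print(m)
  invisible(x)
}

pearson_chi2 <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(NA_real_)
  n * num^2 / den
}

#' Proportional reporting ratio
#'
#' PRR = [a/(a+b)] / [c/(c+d)]. The signal rule is the standard one: at
#' least three co-occurrences (a >= 3), PRR >= 2, and a Pearson chi-square
#' (without continuity correction by default) of at least 4. A zero c cell
#' yields an infinite PRR with the remaining criteria still evaluated.
#'
#' @param table a \code{contingency_table}.
#' @param yates apply the Yates continuity correction to the chi-square.
#' @return object of class \code{signal_score} with \code{score} (the PRR),
#'   \code{chi2} and \code{is_signal}.
#' @export
prr <- function(table, yates = FALSE) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (a + b == 0 || c + d == 0) stopf("empty table margin")
  val <- if (c == 0) Inf else (a / (a + b)) / (c / (c + d))
  chi2 <- pearson_chi2(a, b, c, d, yates = yates)
  sig <- (a >= 3) && (val >= 2) && (!is.na(chi2) && chi2 >= 4)
  structure(list(term = table$term, feature = table$feature, method = "PRR",
                 score = val, chi2 = chi2, is_signal = sig),
            class = "signal_score")
}

#' Reporting odds ratio
#'
#' ROR = (a d)/(b c) with a log-normal 95\% confidence interval
#' (SE of log ROR = sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell triggers
#' the Haldane-Anscombe correction (+0.5 to all four cells). The signal
#' rule: lower 95\% confidence limit above one.
#'
#' @param table a \code{contingency_table}.
#' @return object of class \code{signal_score} with \code{score} (the ROR),
#'   \code{ci_low}, \code{ci_high} and \code{is_signal}.
#' @export
ror <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  val <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(val) + c(-1, 1) * 1.96 * se)
  structure(list(term = table$term, feature = table$feature, method = "ROR",
                 score = val, ci_low = ci[1], ci_high = ci[2],
                 is_signal = ci[1] > 1),
            class = "signal_score")
}

#' @export
print.signal_score <- function(x, ...) {
  extra <- switch(x$method,
                  PRR = sprintf("chi2 = %.2f", x$chi2),
                  ROR = sprintf("95%% CI [%.2f, %.2f]", x$ci_low, x$ci_high),
                  EBGM = sprintf("EB05 = %.2f", x$eb05), "")
  cat(sprintf("%s for '%s': %.3f (%s) -> signal: %s\n", x$method, x$term,
              x$score, extra, x$is_signal))
  invisible(x)
}

expected_count <- function(table) {
  n <- table$a + table$b + table$c + table$d
  (table$a + table$b) * (table$a + table$c) / n
}

# negative log-likelihood of observed counts under the gamma-Poisson
# mixture marginal: a ~ sum_j P_j NegBin(size = alpha_j, prob = beta_j/(beta_j+E))
.ebgm_negll <- function(theta, a, E, components) {
  if (components == 1) {
    al <- exp(theta[1]); be <- exp(theta[2])
    ll <- stats::dnbinom(a, size = al, prob = be / (be + E), log = TRUE)
  } else {
    al1 <- exp(theta[1]); be1 <- exp(theta[2])
    al2 <- exp(theta[3]); be2 <- exp(theta[4])
    P <- stats::plogis(theta[5])
    l1 <- stats::dnbinom(a, size = al1, prob = be1 / (be1 + E), log = TRUE)
    l2 <- stats::dnbinom(a, size = al2, prob = be2 / (be2 + E), log = TRUE)
    m <- pmax(l1, l2)
    ll <- m + log(P * exp(l1 - m) + (1 - P) * exp(l2 - m))
  }
  if (any(!is.finite(ll))) return(1e10)
  -sum(ll)
}

#' Fit the gamma-Poisson shrinker hyperparameters
#'
#' DuMouchel's empirical-Bayes model: the observed count a of each 2x2
#' table is Poisson with mean \eqn{\lambda E}, where E is the expected
#' count under row/column independence, and the reporting-rate multiplier
#' \eqn{\lambda} has a two-component gamma mixture prior
#' \eqn{P\,\Gamma(\alpha_1,\beta_1) + (1-P)\,\Gamma(\alpha_2,\beta_2)}.
#' The hyperparameters maximise the marginal (negative-binomial mixture)
#' likelihood via multi-start bounded quasi-Newton optimisation on a log
#' (logit for P) parameterisation.
#'
#' @param tables list of \code{contingency_table}s, or a data frame with
#'   columns \code{a} and \code{E}; at least 20 tables.
#' @param components 2 for the standard mixture prior, 1 for a single
#'   gamma.
#' @param n_starts number of optimisation starts.
#' @param seed seed for the start jitter.
#' @return object of class \code{ebgm_prior}: list with \code{alpha1},
#'   \code{beta1}, \code{alpha2}, \code{beta2}, \code{P}, \code{loglik},
#'   \code{components}.
#' @export
ebgm_fit <- function(tables, components = 2, n_starts = 5, seed = 1L) {
  if (is.data.frame(tables)) {
    a <- tables$a; E <- tables$E
  } else {
    a <- vapply(tables, `[[`, numeric(1), "a")
    E <- vapply(tables, expected_count, numeric(1))
  }
  ok <- E > 0
  a <- a[ok]; E <- E[ok]
  if (length(a) < 20) stopf("need at least 20 tables with positive E")
  base_starts <- if (components == 1) {
    list(c(0, 0), c(log(2), log(2)), c(log(0.5), log(0.5)))
  } else {
    list(c(0, 0, log(2), log(4), 0),
         c(log(0.2), log(0.1), log(2), log(2), 0),
         c(log(1), log(1), log(5), log(1), qlogis(0.3)))
  }
  npar <- if (components == 1) 2L else 5L
  fits <- list()
  with_seed(seed, {
    starts <- base_starts
    while (length(starts) < n_starts)
      starts[[length(starts) + 1L]] <-
        base_starts[[1]] + stats::rnorm(npar, sd = 1)
    for (s in starts[seq_len(n_starts)]) {
      fit <- tryCatch(
        stats::optim(s, .ebgm_negll, a = a, E = E, components = components,
                     method = "L-BFGS-B", lower = rep(-12, npar),
                     upper = rep(12, npar), control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
    }
  })
  if (!length(fits))
    stopf("EBGM hyperparameter optimisation failed from all %d starts", n_starts)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  th <- best$par
  out <- if (components == 1) {
    list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
         alpha2 = NA_real_, beta2 = NA_real_, P = 1)
  } else {
    list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
         alpha2 = exp(th[3]), beta2 = exp(th[4]),
         P = stats::plogis(th[5]))
  }
  out$loglik <- -best$value
  out$components <- components
  out$n_tables <- length(a)
  structure(out, class = "ebgm_prior")
}

#' @export
print.ebgm_prior <- function(x, ...) {
  cat(sprintf("Gamma-Poisson shrinker prior (%d component%s, %d tables)\n",
              x$components, if (x$components > 1) "s" else "", x$n_tables))
  cat(sprintf("  alpha1 = %.4g, beta1 = %.4g", x$alpha1, x$beta1))
  if (x$components == 2)
    cat(sprintf("; alpha2 = %.4g, beta2 = %.4g; P = %.3f",
                x$alpha2, x$beta2, x$P))
  cat(sprintf("\n  log-likelihood %.2f\n", x$loglik))
  invisible(x)
}

# posterior mixture over lambda given (a, E): component j becomes
# Gamma(alpha_j + a, beta_j + E) with weight proportional to
# P_j * NegBin(a; alpha_j, beta_j/(beta_j+E))
ebgm_posterior <- function(a, E, prior) {
  if (prior$components == 1) {
    list(w = 1, shape = prior$alpha1 + a, rate = prior$beta1 + E)
  } else {
    l1 <- stats::dnbinom(a, size = prior$alpha1,
                         prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
    l2 <- stats::dnbinom(a, size = prior$alpha2,
                         prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
    lw <- c(log(prior$P) + l1, log(1 - prior$P) + l2)
    w <- exp(lw - max(lw)); w <- w / sum(w)
    list(w = w, shape = c(prior$alpha1, prior$alpha2) + a,
         rate = c(prior$beta1, prior$beta2) + E)
  }
}

#' Score a table with the fitted gamma-Poisson shrinker
#'
#' EBGM is the empirical-Bayes geometric mean
#' \eqn{\exp(E[\log\lambda \mid a])} of the posterior reporting-rate
#' multiplier; EB05 its lower one-sided 95\% limit (5th posterior
#' percentile, found by bisection on the mixture CDF). Signal rule:
#' EB05 >= 2.
#'
#' @param table a \code{contingency_table}.
#' @param prior fitted \code{\link{ebgm_fit}} hyperparameters.
#' @return object of class \code{signal_score} with \code{score} (EBGM),
#'   \code{eb05} and \code{is_signal}.
#' @export
ebgm_score <- function(table, prior) {
  a <- table$a
  E <- expected_count(table)
  post <- ebgm_posterior(a, E, prior)
  eb_log <- sum(post$w * (digamma(post$shape) - log(post$rate)))
  ebgm <- exp(eb_log)
  cdf <- function(x) sum(post$w * stats::pgamma(x, post$shape, post$rate))
  lo <- 0; hi <- max(stats::qgamma(0.999, post$shape, post$rate))
  eb05 <- stats::uniroot(function(x) cdf(x) - 0.05, c(lo, hi),
                         tol = 1e-10)$root
  structure(list(term = table$term, feature = table$feature, method = "EBGM",
                 score = ebgm, eb05 = eb05, E = E, a = a,
                 is_signal = eb05 >= 2),
            class = "signal_score")
}

#' Score every term of every non-endpoint feature with PRR/ROR/EBGM
#'
#' Convenience wrapper building all contingency tables once, fitting the
#' shrinker on them, and returning one row per term and method.
#'
#' @inheritParams infer_causes
#' @param methods subset of \code{c("PRR", "ROR", "EBGM")}.
#' @return data frame with columns \code{feature}, \code{term},
#'   \code{method}, \code{score}, \code{aux} (chi2 / ci_low / eb05) and
#'   \code{is_signal}.
#' @export
score_signals <- function(reports, schema, methods = c("PRR", "ROR", "EBGM"),
                          min_count = 1) {
  feats <- setdiff(schema$features, schema$endpoint_feature)
  tables <- list()
  for (f in feats)
    for (term in schema$vocab[[f]])
      tables[[paste(f, term, sep = ": ")]] <-
        build_contingency(reports, term, f, schema)
  prior <- if ("EBGM" %in% methods) ebgm_fit(tables) else NULL
  rows <- list()
  for (key in names(tables)) {
    tb <- tables[[key]]
    if (tb$a + tb$b < min_count) next
    for (m in methods) {
      sc <- switch(m, PRR = prr(tb), ROR = ror(tb),
                   EBGM = ebgm_score(tb, prior))
      rows[[length(rows) + 1L]] <-
        data.frame(feature = tb$feature, term = tb$term, method = m,
                   score = sc$score,
                   aux = switch(m, PRR = sc$chi2, ROR = sc$ci_low,
                                EBGM = sc$eb05),
                   is_signal = sc$is_signal, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Compare interventional enrichment with conventional signal sets
#'
#' Takes the enriched term set of the classifier probe and the signal sets
#' of the conventional methods (all as \code{"feature: term"} labels over a
#' shared universe) and tallies per-method counts plus every intersection
#' region — the data behind a four-way Venn comparison.
#'
#' @param sets named list of character vectors (e.g. \code{probe}, \code{PRR},
#'   \code{ROR}, \code{EBGM}).
#' @param universe character vector of all candidate labels; every set must
#'   be a subset of it.
#' @return list with \code{counts} (per-method sizes), \code{regions}
#'   (membership-pattern tallies) and \code{pairwise} intersection sizes.
#' @export
compare_signal_sets <- function(sets, universe) {
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], universe)
    if (length(extra))
      stopf("set '%s' contains labels outside the shared universe: %s",
            nm, paste(extra, collapse = ", "))
  }
  k <- length(sets)
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) paste(as.integer(m), collapse = ""))
  regions <- table(pattern[rowSums(member) > 0])
  pairs <- utils::combn(names(sets), 2)
  pairwise <- apply(pairs, 2, function(pr)
    length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
  names(pairwise) <- apply(pairs, 2, paste, collapse = " & ")
  list(counts = lengths(sets),
       regions = stats::setNames(as.integer(regions), names(regions)),
       pairwise = pairwise,
       all_methods = Reduce(intersect, sets))
}
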