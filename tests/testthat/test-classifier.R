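test_that("encoder backprop matches finite-difference gradients", {
  cfg <- classifier_config("transformer", max_seq_len = 5, hidden_size = 4,
                           n_layers = 2, n_heads = 2, ff_size = 6,
                           total_steps = 2, checkpoint_every = 1, seed = 3)
  vocab <- c("<oov>", "a", "b", "c", "d")
  params <- pvprobe:::encoder_init(length(vocab), cfg)
  texts <- c("a b c", "d a", "c c b a")
  labels <- c(1, 0, 1)
  lg <- pvprobe:::encoder_loss_grads(params, texts, labels, vocab, cfg)
  get_at <- function(p, idx) { for (k in idx) p <- p[[k]]; p }
  set_at <- function(p, idx, val) {
    if (length(idx) == 1) { p[[idx[[1]]]] <- val; return(p) }
    p[[idx[[1]]]] <- set_at(p[[idx[[1]]]], idx[-1], val)
    p
  }
  paths <- list(list("E"), list("P"), list("Wc"), list("bc"),
                list("layers", 1L, "Wq"), list("layers", 1L, "Wk"),
                list("layers", 2L, "Wv"), list("layers", 1L, "Wo"),
                list("layers", 1L, "g1"), list("layers", 2L, "b2"),
                list("layers", 2L, "W1"), list("layers", 1L, "W2"),
                list("layers", 2L, "bf1"))
  eps <- 1e-5
  pvprobe:::with_seed(9, {
    for (pth in paths) {
      M <- get_at(params, pth)
      analytic <- get_at(lg$grads, pth)
      for (rep in 1:3) {
        i <- sample(length(M), 1)
        Mp <- M; Mp[i] <- M[i] + eps
        l1 <- pvprobe:::encoder_loss_grads(set_at(params, pth, Mp), texts,
                                           labels, vocab, cfg)$loss
        Mp[i] <- M[i] - eps
        l2 <- pvprobe:::encoder_loss_grads(set_at(params, pth, Mp), texts,
                                           labels, vocab, cfg)$loss
        numeric_g <- (l1 - l2) / (2 * eps)
        expect_lt(abs(numeric_g - analytic[i]),
                  1e-4 * max(1, abs(numeric_g) + abs(analytic[i])) + 1e-8)
      }
    }
  })
})

test_that("token-logistic separates a perfectly predictive token and is deterministic", {
  tr <- separable_corpus(240, seed = 2)
  dv <- separable_corpus(100, seed = 3)
  cfg <- classifier_config("token-logistic", seed = 7)
  m1 <- fit_endpoint_classifier(tr, dv, cfg)
  expect_equal(m1$dev_accuracy, 1.0)
  # trace invariants
  expect_true(all(diff(m1$trace$step) > 0))
  expect_true(all(m1$trace$dev_accuracy >= 0 & m1$trace$dev_accuracy <= 1))
  # checkpoint selection: returned accuracy is the trace maximum, earliest tie
  expect_equal(m1$dev_accuracy, max(m1$trace$dev_accuracy))
  expect_equal(m1$best_step,
               m1$trace$step[which.max(m1$trace$dev_accuracy)])
  # bitwise determinism
  m2 <- fit_endpoint_classifier(tr, dv, cfg)
  expect_identical(m1$params$w, m2$params$w)
  expect_identical(m1$trace, m2$trace)
  # the separating token carries the largest coefficient
  expect_identical(names(which.max(coef(m1))), "toxin")
})

test_that("single-class training data is rejected", {
  tr <- separable_corpus(50, seed = 2)
  tr$label <- 1L
  expect_error(fit_endpoint_classifier(tr, tr, classifier_config()),
               "single class")
})

test_that("transformer reaches the token-logistic oracle on separable data", {
  tr <- separable_corpus(240, seed = 4)
  dv <- separable_corpus(100, seed = 5)
  oracle <- fit_endpoint_classifier(tr, dv, classifier_config("token-logistic"))
  expect_equal(oracle$dev_accuracy, 1.0)
  m <- fit_endpoint_classifier(tr, dv, small_transformer_config(seed = 5))
  expect_gte(m$dev_accuracy, 0.95)
  # numerically reproducible under the same seed
  m2 <- fit_endpoint_classifier(tr, dv, small_transformer_config(seed = 5))
  expect_equal(m$dev_accuracy, m2$dev_accuracy, tolerance = 1e-6)
  expect_equal(m$trace$dev_loss, m2$trace$dev_loss, tolerance = 1e-6)
})

test_that("permuted labels give chance-level best dev accuracy", {
  tr <- separable_corpus(400, seed = 6)
  dv <- separable_corpus(400, seed = 7)
  pvprobe:::with_seed(8, {
    tr$label <- sample(tr$label)
    dv$label <- sample(dv$label)
  })
  m <- fit_endpoint_classifier(tr, dv, classifier_config("token-logistic",
                                                         seed = 8))
  majority <- max(mean(dv$label), 1 - mean(dv$label))
  expect_lt(abs(m$dev_accuracy - majority), 0.05)
})

test_that("predictions are probabilities, deterministic, and OOV-safe", {
  tr <- separable_corpus(240, seed = 2)
  dv <- separable_corpus(100, seed = 3)
  m <- fit_endpoint_classifier(tr, dv, classifier_config("token-logistic"))
  p <- predict(m, c("alpha toxin beta", "alpha toxin beta",
                    "nevertokenised words only"))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p[[1]], p[[2]])
  # separable data: positives get higher mean probability
  pd <- predict(m, dv)
  expect_gt(mean(pd[dv$label == 1]), mean(pd[dv$label == 0]))
  expect_named(pd, dv$report_id)
})

test_that("cross-entropy matches hand computation and is monotone", {
  expect_equal(cross_entropy(c(1, 1), c(1, 1))$sum, 0)
  ce <- cross_entropy(c(0.5, 0.5), c(1, 0))
  expect_equal(ce$sum, -2 * log(0.5), tolerance = 1e-12)
  expect_equal(ce$mean, log(2), tolerance = 1e-12)
  # increasing any true-class probability decreases the loss
  base <- cross_entropy(c(0.6, 0.3), c(1, 0))$sum
  expect_lt(cross_entropy(c(0.7, 0.3), c(1, 0))$sum, base)
  expect_lt(cross_entropy(c(0.6, 0.2), c(1, 0))$sum, base)
  expect_error(cross_entropy(0.5, c(1, 0)), "mismatch")
})

test_that("accuracy is a step function of the threshold", {
  recs <- separable_corpus(60, seed = 9)
  m <- fit_endpoint_classifier(recs, recs, classifier_config("token-logistic"))
  expect_equal(evaluate_accuracy(m, recs), 1.0)
  wrong <- recs; wrong$label <- 1L - wrong$label
  expect_equal(evaluate_accuracy(m, wrong), 0.0)
  p <- predict(m, recs)
  grid <- sort(unique(c(0, p, 1)))
  acc <- vapply(grid, function(t) mean((p >= t) == (recs$label == 1)),
                numeric(1))
  # at most one jump per distinct probability value
  expect_lte(sum(diff(acc) != 0), length(unique(p)))
  expect_error(evaluate_accuracy(m, recs[0, ]), "empty")
})

test_that("both classifier kinds drive the probe to the same planted cause", {
  sim <- default_sim_config(900, seed = 13, missing_rate = 0.05)
  sim$effects <- c(APAP = 6)
  sim$intercept <- -3
  sim$interaction_effects <- NULL
  recovered <- lapply(c("token-logistic", "transformer"), function(kind) {
    clf <- if (kind == "transformer")
      classifier_config("transformer", max_seq_len = 24, hidden_size = 16,
                        n_layers = 2, n_heads = 2, ff_size = 32,
                        batch_size = 16, total_steps = 150,
                        checkpoint_every = 25, seed = 13)
    else classifier_config("token-logistic", seed = 13)
    run <- probe_run(sim, kind = kind, seed = 13, clf = clf)
    top_drug <- attr(run$terms, "root_causes")
    top_drug$term[top_drug$feature == "primary suspect drug"]
  })
  expect_identical(recovered[[1]], "APAP")
  expect_identical(recovered[[2]], "APAP")
})
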