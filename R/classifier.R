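#' Classifier configuration
#'
#' Settings for the probabilistic endpoint classifier. Two interchangeable
#' kinds implement the same contract: \code{"token-logistic"}, a logistic
#' regression on bag-of-token counts trained by full-batch Adam (fast and
#' bitwise deterministic), and \code{"transformer"}, a compact bidirectional
#' self-attention encoder with a CLS-token softmax head trained from scratch
#' on the corpus vocabulary. Checkpoints are evaluated on the development
#' split every \code{checkpoint_every} steps and the returned model is the
#' checkpoint with maximum dev accuracy (earliest step on ties).
#'
#' @param kind classifier kind.
#' @param max_seq_len maximum token length; longer sentences are truncated.
#' @param batch_size minibatch size (transformer; the token-logistic model
#'   is fitted full-batch).
#' @param total_steps number of optimisation steps.
#' @param warmup_steps linear learning-rate warmup steps.
#' @param checkpoint_every evaluate the dev split every this many steps.
#' @param learning_rate peak Adam learning rate.
#' @param hidden_size,n_layers,n_heads,ff_size transformer dimensions.
#' @param seed integer seed for initialisation and batch sampling.
#' @return object of class \code{classifier_config}.
#' @export
classifier_config <- function(kind = c("token-logistic", "transformer"),
                              max_seq_len = 64L,
                              batch_size = 32L,
                              total_steps = if (match.arg(kind) == "transformer") 300L else 200L,
                              warmup_steps = max(1L, round(total_steps / 10)),
                              checkpoint_every = max(1L, round(total_steps / 10)),
                              learning_rate = if (match.arg(kind) == "transformer") 2e-3 else 0.2,
                              hidden_size = 32L, n_layers = 2L, n_heads = 2L,
                              ff_size = 64L, seed = 1L) {
  kind <- match.arg(kind)
  if (checkpoint_every > total_steps)
    stopf("checkpoint_every must be <= total_steps")
  if (hidden_size %% n_heads != 0)
    stopf("hidden_size must be divisible by n_heads")
  structure(list(kind = kind, max_seq_len = as.integer(max_seq_len),
                 batch_size = as.integer(batch_size),
                 total_steps = as.integer(total_steps),
                 warmup_steps = as.integer(warmup_steps),
                 checkpoint_every = as.integer(checkpoint_every),
                 learning_rate = learning_rate,
                 hidden_size = as.integer(hidden_size),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 ff_size = as.integer(ff_size),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# whitespace + lowercase tokenizer with light punctuation stripping
tokenize_text <- function(x) {
  x <- gsub("[,.;:!?\"']", " ", tolower(x))
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

build_vocab <- function(texts) {
  toks <- sort(unique(unlist(lapply(texts, tokenize_text))))
  c("<oov>", toks)
}

# bag-of-token count matrix over vocab (column 1 = OOV bucket)
token_count_matrix <- function(texts, vocab) {
  X <- matrix(0, length(texts), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(texts)) {
    toks <- tokenize_text(texts[i])
    idx <- match(toks, vocab)
    idx[is.na(idx)] <- 1L  # OOV bucket
    tab <- tabulate(idx, nbins = length(vocab))
    X[i, ] <- tab
  }
  X
}

adam_init <- function(params) {
  zeros <- rapply(params, function(p) array(0, dim = dim(p) %||% length(p)),
                  how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

lr_at <- function(step, config) {
  if (step <= config$warmup_steps)
    config$learning_rate * step / config$warmup_steps
  else config$learning_rate
}

#' Fit the endpoint classifier with dev-based checkpoint selection
#'
#' Trains the configured classifier on the training split, evaluating
#' cross-entropy loss and accuracy on the development split at every
#' checkpoint. The returned model is restored to the checkpoint with the
#' highest dev accuracy (ties resolved to the earliest step), and the full
#' training trace is attached for inspection.
#'
#' @param train,dev sentence data frames with \code{text} and \code{label};
#'   the training split must contain both classes.
#' @param config a \code{\link{classifier_config}}.
#' @return object of class \code{endpoint_classifier} with elements
#'   \code{kind}, \code{vocab}, \code{params}, \code{trace} (data frame of
#'   step/dev_loss/dev_accuracy), \code{best_step}, \code{dev_accuracy}.
#' @export
fit_endpoint_classifier <- function(train, dev, config = classifier_config()) {
  if (nrow(train) == 0 || nrow(dev) == 0) stopf("empty training or dev split")
  if (length(unique(train$label)) < 2)
    stopf("training split contains a single class")
  vocab <- build_vocab(train$text)
  fitter <- switch(config$kind,
                   "token-logistic" = fit_token_logistic,
                   "transformer" = fit_transformer)
  fit <- fitter(train, dev, vocab, config)
  structure(list(kind = config$kind, vocab = vocab, params = fit$params,
                 config = config, trace = fit$trace,
                 best_step = fit$best_step,
                 dev_accuracy = fit$dev_accuracy),
            class = "endpoint_classifier")
}

# checkpoint bookkeeping shared by both kinds: returns the trace row and
# updates best-so-far (strict > keeps the earliest step on ties)
.eval_checkpoint <- function(step, probs_dev, labels_dev) {
  ce <- cross_entropy(probs_dev, labels_dev)
  acc <- mean((probs_dev >= 0.5) == (labels_dev == 1))
  data.frame(step = step, dev_loss = ce$mean, dev_accuracy = acc)
}

fit_token_logistic <- function(train, dev, vocab, config) {
  X <- cbind(`(intercept)` = 1, token_count_matrix(train$text, vocab))
  Xd <- cbind(`(intercept)` = 1, token_count_matrix(dev$text, vocab))
  y <- as.numeric(train$label)
  w <- rep(0, ncol(X))
  st <- adam_init(list(w = w))
  trace <- NULL
  best <- list(acc = -Inf, step = NA_integer_, w = w)
  for (step in seq_len(config$total_steps)) {
    p <- sigmoid(drop(X %*% w))
    g <- drop(crossprod(X, p - y)) / nrow(X)
    res <- adam_step(list(w = w), list(w = g), st, lr_at(step, config))
    w <- res$params$w
    st <- res$state
    if (step %% config$checkpoint_every == 0 || step == config$total_steps) {
      pd <- sigmoid(drop(Xd %*% w))
      row <- .eval_checkpoint(step, pd, dev$label)
      trace <- rbind(trace, row)
      if (row$dev_accuracy > best$acc)
        best <- list(acc = row$dev_accuracy, step = step, w = w)
    }
  }
  list(params = list(w = stats::setNames(best$w, colnames(X))),
       trace = trace, best_step = best$step, dev_accuracy = best$acc)
}

#' Predict endpoint probabilities for sentence records
#'
#' Deterministic evaluation-mode forward pass; unseen tokens fall into the
#' out-of-vocabulary bucket.
#'
#' @param object a fitted \code{endpoint_classifier}.
#' @param newdata sentence data frame (with \code{text}, and optionally
#'   \code{report_id} used to name the result) or a character vector.
#' @param ... unused.
#' @return named numeric vector of positive-endpoint probabilities, one per
#'   record (the model's conditional probability table).
#' @export
predict.endpoint_classifier <- function(object, newdata, ...) {
  texts <- if (is.character(newdata)) newdata else newdata$text
  ids <- if (!is.character(newdata) && !is.null(newdata$report_id))
    newdata$report_id else as.character(seq_along(texts))
  p <- switch(object$kind,
    "token-logistic" = {
      X <- cbind(1, token_count_matrix(texts, object$vocab))
      sigmoid(drop(X %*% unname(object$params$w)))
    },
    "transformer" = transformer_predict(object$params, texts, object$vocab,
                                        object$config))
  stats::setNames(pmin(pmax(p, 0), 1), ids)
}

#' @export
print.endpoint_classifier <- function(x, ...) {
  cat(sprintf("Endpoint classifier (%s)\n", x$kind))
  cat(sprintf("  vocabulary: %d tokens\n", length(x$vocab)))
  cat(sprintf("  selected checkpoint: step %d (dev accuracy %.3f)\n",
              x$best_step, x$dev_accuracy))
  invisible(x)
}

#' @export
summary.endpoint_classifier <- function(object, ...) {
  cat(sprintf("Endpoint classifier (%s), %d checkpoints\n",
              object$kind, nrow(object$trace)))
  print(object$trace, row.names = FALSE)
  invisible(object$trace)
}

#' @export
coef.endpoint_classifier <- function(object, ...) {
  if (object$kind == "token-logistic") object$params$w
  else unlist(lapply(object$params, function(p)
    if (is.list(p)) lapply(p, length) else length(p)))
}

#' Cross-entropy loss of predicted probabilities
#'
#' Natural-log cross-entropy of the predicted positive-class probabilities
#' against 0/1 labels; the probability of the true class is clamped at
#' \code{1e-12} before taking logs. Both the summed and per-instance mean
#' loss are returned.
#'
#' @param probs predicted positive-class probabilities.
#' @param labels 0/1 labels of the same length.
#' @return list with \code{sum} and \code{mean}.
#' @export
cross_entropy <- function(probs, labels) {
  if (length(probs) != length(labels)) stopf("length mismatch")
  p_true <- ifelse(labels == 1, probs, 1 - probs)
  p_true <- pmax(p_true, 1e-12)
  ll <- -log(p_true)
  list(sum = sum(ll), mean = mean(ll))
}

#' Classification accuracy of a fitted model on records
#'
#' @param model a fitted \code{endpoint_classifier}.
#' @param records sentence data frame with \code{text} and \code{label}.
#' @param threshold decision threshold on the positive probability.
#' @return fraction of records classified correctly.
#' @export
evaluate_accuracy <- function(model, records, threshold = 0.5) {
  if (nrow(records) == 0) stopf("empty record set")
  p <- predict(model, records)
  mean((p >= threshold) == (records$label == 1))
}
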