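# Compact bidirectional self-attention text encoder with a CLS softmax head.
# Forward and reverse passes are written directly in base R (the analytic
# gradients are verified against finite differences in the test suite).
# Architecture per layer: multi-head self-attention + residual + layer norm,
# then a ReLU feed-forward block + residual + layer norm; the classification
# head reads the first (CLS) position of the last layer.

.ln_eps <- 1e-5

encoder_init <- function(vocab_size, config) {
  d <- config$hidden_size
  dff <- config$ff_size
  L <- config$max_seq_len + 1L  # +1 for the CLS slot
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  with_seed(config$seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = rn(d, d), Wk = rn(d, d), Wv = rn(d, d), Wo = rn(d, d),
           g1 = rep(1, d), b1 = rep(0, d),
           W1 = rn(d, dff), bf1 = rep(0, dff),
           W2 = rn(dff, d), bf2 = rep(0, d),
           g2 = rep(1, d), b2 = rep(0, d))
    })
    list(E = rn(vocab_size + 1L, d),  # +1 row for the CLS token embedding
         P = rn(L, d),
         Wc = rn(d, 2), bc = rep(0, 2),
         layers = layers)
  })
}

encoder_zero_grads <- function(params) {
  rapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else rep(0, length(p))
  }, how = "replace")
}

# token ids for one sentence: CLS id is nrow(E) (the extra embedding row),
# OOV id is 1 (vocab[1] == "<oov>")
encode_ids <- function(text, vocab, config) {
  toks <- tokenize_text(text)
  if (length(toks) > config$max_seq_len)
    toks <- toks[seq_len(config$max_seq_len)]
  idx <- match(toks, vocab)
  idx[is.na(idx)] <- 1L
  c(length(vocab) + 1L, idx)  # prepend CLS
}

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + .ln_eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, g, `*`)
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, xhat = xhat, inv = inv, xc = xc)
}

ln_bwd <- function(dY, cache, g) {
  D <- ncol(dY)
  dxhat <- sweep(dY, 2, g, `*`)
  # standard layer-norm backward (per row)
  term1 <- dxhat
  term2 <- rowMeans(dxhat)
  term3 <- cache$xhat * rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (term1 - term2 - term3)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  e <- exp(S - m)
  e / rowSums(e)
}

encoder_forward <- function(params, ids, config, need_cache = TRUE) {
  d <- config$hidden_size
  h <- config$n_heads
  dh <- d %/% h
  Tn <- length(ids)
  X <- params$E[ids, , drop = FALSE] + params$P[seq_len(Tn), , drop = FALSE]
  caches <- vector("list", config$n_layers)
  X0 <- X
  for (l in seq_len(config$n_layers)) {
    W <- params$layers[[l]]
    Xin <- X
    Q <- Xin %*% W$Wq; K <- Xin %*% W$Wk; V <- Xin %*% W$Wv
    H <- matrix(0, Tn, d)
    heads <- vector("list", h)
    for (j in seq_len(h)) {
      cols <- ((j - 1) * dh + 1):(j * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      A <- softmax_rows(S)
      H[, cols] <- A %*% V[, cols, drop = FALSE]
      heads[[j]] <- A
    }
    O <- H %*% W$Wo
    R1 <- Xin + O
    ln1 <- ln_fwd(R1, W$g1, W$b1)
    X1 <- ln1$Y
    F1pre <- sweep(X1 %*% W$W1, 2, W$bf1, `+`)
    F1 <- pmax(F1pre, 0)
    F2 <- sweep(F1 %*% W$W2, 2, W$bf2, `+`)
    R2 <- X1 + F2
    ln2 <- ln_fwd(R2, W$g2, W$b2)
    X <- ln2$Y
    if (need_cache)
      caches[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, heads = heads,
                          H = H, ln1 = ln1, X1 = X1, F1pre = F1pre, F1 = F1,
                          ln2 = ln2)
  }
  logits <- drop(X[1, ] %*% params$Wc) + params$bc
  m <- max(logits)
  p <- exp(logits - m); p <- p / sum(p)
  list(probs = p, Xlast = X, caches = caches, X0 = X0, ids = ids)
}

# gradient of the CE loss of one sequence w.r.t. all parameters, added into
# `grads` in place (returns the updated list)
encoder_backward <- function(params, fwd, label, config, grads) {
  d <- config$hidden_size
  h <- config$n_heads
  dh <- d %/% h
  Tn <- length(fwd$ids)
  dlogits <- fwd$probs
  dlogits[label + 1L] <- dlogits[label + 1L] - 1
  grads$Wc <- grads$Wc + tcrossprod(fwd$Xlast[1, ], dlogits)
  grads$bc <- grads$bc + dlogits
  dX <- matrix(0, Tn, d)
  dX[1, ] <- drop(params$Wc %*% dlogits)
  for (l in rev(seq_len(config$n_layers))) {
    W <- params$layers[[l]]
    cc <- fwd$caches[[l]]
    g <- grads$layers[[l]]
    bl2 <- ln_bwd(dX, cc$ln2, W$g2)
    g$g2 <- g$g2 + bl2$dg; g$b2 <- g$b2 + bl2$db
    dR2 <- bl2$dX
    dX1 <- dR2
    dF2 <- dR2
    g$W2 <- g$W2 + crossprod(cc$F1, dF2)
    g$bf2 <- g$bf2 + colSums(dF2)
    dF1 <- dF2 %*% t(W$W2)
    dF1[cc$F1pre <= 0] <- 0
    g$W1 <- g$W1 + crossprod(cc$X1, dF1)
    g$bf1 <- g$bf1 + colSums(dF1)
    dX1 <- dX1 + dF1 %*% t(W$W1)
    bl1 <- ln_bwd(dX1, cc$ln1, W$g1)
    g$g1 <- g$g1 + bl1$dg; g$b1 <- g$b1 + bl1$db
    dR1 <- bl1$dX
    dXin <- dR1
    dO <- dR1
    g$Wo <- g$Wo + crossprod(cc$H, dO)
    dH <- dO %*% t(W$Wo)
    dQ <- matrix(0, Tn, d); dK <- matrix(0, Tn, d); dV <- matrix(0, Tn, d)
    for (j in seq_len(h)) {
      cols <- ((j - 1) * dh + 1):(j * dh)
      A <- cc$heads[[j]]
      dHj <- dH[, cols, drop = FALSE]
      Vj <- cc$V[, cols, drop = FALSE]
      dA <- tcrossprod(dHj, Vj)
      dV[, cols] <- crossprod(A, dHj)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    g$Wq <- g$Wq + crossprod(cc$Xin, dQ)
    g$Wk <- g$Wk + crossprod(cc$Xin, dK)
    g$Wv <- g$Wv + crossprod(cc$Xin, dV)
    dXin <- dXin + dQ %*% t(W$Wq) + dK %*% t(W$Wk) + dV %*% t(W$Wv)
    grads$layers[[l]] <- g
    dX <- dXin
  }
  # embeddings and positions
  for (t in seq_len(Tn)) {
    grads$E[fwd$ids[t], ] <- grads$E[fwd$ids[t], ] + dX[t, ]
  }
  grads$P[seq_len(Tn), ] <- grads$P[seq_len(Tn), , drop = FALSE] +
    dX
  grads
}

encoder_loss_grads <- function(params, texts, labels, vocab, config) {
  grads <- encoder_zero_grads(params)
  loss <- 0
  n <- length(texts)
  for (i in seq_len(n)) {
    ids <- encode_ids(texts[i], vocab, config)
    fwd <- encoder_forward(params, ids, config)
    p_true <- max(fwd$probs[labels[i] + 1L], 1e-12)
    loss <- loss - log(p_true)
    grads <- encoder_backward(params, fwd, labels[i], config, grads)
  }
  scale <- function(x) x / n
  list(loss = loss / n, grads = rapply(grads, scale, how = "replace"))
}

transformer_predict <- function(params, texts, vocab, config) {
  vapply(texts, function(tx) {
    fwd <- encoder_forward(params, encode_ids(tx, vocab, config), config,
                           need_cache = FALSE)
    fwd$probs[2]
  }, numeric(1), USE.NAMES = FALSE)
}

fit_transformer <- function(train, dev, vocab, config) {
  params <- encoder_init(length(vocab), config)
  st <- adam_init(params)
  n <- nrow(train)
  trace <- NULL
  best <- list(acc = -Inf, step = NA_integer_, params = params)
  with_seed(config$seed + 1L, {
    for (step in seq_len(config$total_steps)) {
      idx <- sample.int(n, min(config$batch_size, n))
      lg <- encoder_loss_grads(params, train$text[idx], train$label[idx],
                               vocab, config)
      res <- adam_step(params, lg$grads, st, lr_at(step, config))
      params <- res$params
      st <- res$state
      if (step %% config$checkpoint_every == 0 || step == config$total_steps) {
        pd <- transformer_predict(params, dev$text, vocab, config)
        row <- .eval_checkpoint(step, pd, dev$label)
        trace <- rbind(trace, row)
        if (row$dev_accuracy > best$acc)
          best <- list(acc = row$dev_accuracy, step = step, params = params)
      }
    }
  })
  list(params = best$params, trace = trace, best_step = best$step,
       dev_accuracy = best$acc)
}
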