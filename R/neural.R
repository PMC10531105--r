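# Neural sequence classifiers: a small transformer encoder with a learned CLS
# vector, a Bi-LSTM with the classic 64->4 dense head, a 1-d CNN with global
# max-pooling, and a `pretrained_adapter` seam that accepts any external
# text-to-vector encoder and trains only a linear head on top of it.

#' Describe a neural encoder architecture
#'
#' Defaults are deliberately small (CPU-scale): the transformer uses 2 layers,
#' 4 heads, model dimension 64 and feed-forward width 128; the Bi-LSTM head has
#' a 64-unit dense layer followed by the 4-class output layer; the CNN applies
#' a 1-d convolution followed by global max-pooling and the same head.
#' Full-scale pretrained checkpoints plug in through `kind =
#' "pretrained_adapter"` with `encode_fn` mapping a text to a fixed-length
#' numeric vector.
#'
#' @param kind One of "tiny_transformer", "bilstm", "cnn", "pretrained_adapter".
#' @param embedding_dim Token embedding size (default 64).
#' @param hidden_size Per-direction LSTM width (default 32, so the
#'   concatenated Bi-LSTM state has 64 units).
#' @param n_layers,n_heads,ff_dim Transformer depth, heads, feed-forward width.
#' @param kernel_size,n_filters CNN window and filter count.
#' @param dense_units Width of the penultimate dense layer (default 64).
#' @param max_seq_len Truncation length for tokenized conclusions (default 64).
#' @param vocab_cap Tokenizer vocabulary cap (default unlimited).
#' @param encode_fn,adapter_dim External encoder callback and its output
#'   dimension (adapter kind only).
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(kind = c("tiny_transformer", "bilstm", "cnn", "pretrained_adapter"),
                         embedding_dim = 64L, hidden_size = 32L,
                         n_layers = 2L, n_heads = 4L, ff_dim = 128L,
                         kernel_size = 3L, n_filters = 64L, dense_units = 64L,
                         max_seq_len = 64L, vocab_cap = Inf,
                         encode_fn = NULL, adapter_dim = NULL) {
  kind <- match.arg(kind)
  if (embedding_dim < 1L || max_seq_len < 1L) stop("dimensions must be positive")
  if (kind == "tiny_transformer" && embedding_dim %% n_heads != 0L) {
    stop("embedding_dim must be divisible by n_heads")
  }
  if (kind == "pretrained_adapter" && (is.null(encode_fn) || is.null(adapter_dim))) {
    stop("pretrained_adapter requires encode_fn and adapter_dim")
  }
  structure(list(kind = kind, embedding_dim = embedding_dim,
                 hidden_size = hidden_size, n_layers = n_layers,
                 n_heads = n_heads, ff_dim = ff_dim,
                 kernel_size = kernel_size, n_filters = n_filters,
                 dense_units = dense_units, max_seq_len = max_seq_len,
                 vocab_cap = vocab_cap, encode_fn = encode_fn,
                 adapter_dim = adapter_dim),
            class = "encoder_spec")
}

#' Training configuration for the neural classifiers
#'
#' @param epochs Training epochs (default 10).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Gradient-accumulation batch size (default 8).
#' @param eval_batch_size Evaluation chunk size (kept for interface symmetry;
#'   evaluation is sequential).
#' @param seeds Integer seeds for multi-seed experiments (default 1:3).
#' @param patience Early-stopping patience on dev accuracy (default Inf).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10L, learning_rate = 1e-3, batch_size = 8L,
                         eval_batch_size = 32L, seeds = c(1L, 2L, 3L),
                         patience = Inf) {
  if (epochs < 0L || batch_size < 1L || learning_rate <= 0) stop("invalid train_config")
  if (!length(seeds)) stop("need at least one seed")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, eval_batch_size = eval_batch_size,
                 seeds = as.integer(seeds), patience = patience),
            class = "train_config")
}

#' Augmentation configuration for consistency training
#'
#' @param P Permuted variants per conclusion (default 10).
#' @param seed Seed for variant sampling.
#' @param max_attempts Rejection-sampling cap, default `100 * P`.
#' @param include_variants_in_ce Also feed permuted variants to the
#'   cross-entropy term as labeled samples (default TRUE).
#' @param average_all_variants Average the consistency loss over all P variants
#'   instead of sampling one per step (default FALSE).
#' @param stop_gradient_original Treat the original's distribution as a
#'   constant in the consistency term (default FALSE: gradient flows through
#'   both distributions).
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(P = 10L, seed = 1L, max_attempts = 100L * P,
                                include_variants_in_ce = TRUE,
                                average_all_variants = FALSE,
                                stop_gradient_original = FALSE) {
  if (P < 1L) stop("P must be >= 1")
  structure(list(P = as.integer(P), seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts),
                 include_variants_in_ce = include_variants_in_ce,
                 average_all_variants = average_all_variants,
                 stop_gradient_original = stop_gradient_original),
            class = "augmentation_config")
}

#' Weights of the combined training objective
#'
#' @param alpha Cross-entropy weight (default 1).
#' @param beta Consistency-loss weight (default 10).
#' @return A `consistency_weights` list.
#' @export
consistency_weights <- function(alpha = 1, beta = 10) {
  if (alpha < 0 || beta < 0) stop("weights must be non-negative")
  if (alpha == 0 && beta == 0) stop("alpha and beta must not both be zero")
  structure(list(alpha = alpha, beta = beta), class = "consistency_weights")
}

# ---- parameter initialization and forward/backward per architecture ------

init_classifier_params <- function(spec, V) {
  d <- spec$embedding_dim
  switch(spec$kind,
    tiny_transformer = list(
      emb = rand_mat(V, d),
      cls = stats::runif(d, -0.08, 0.08),
      enc = init_tf_encoder(d, spec$n_layers, spec$n_heads, spec$ff_dim),
      Wout = rand_mat(d, 4L), bout = rep(0, 4)
    ),
    bilstm = list(
      emb = rand_mat(V, d),
      fw = init_lstm(d, spec$hidden_size),
      bw = init_lstm(d, spec$hidden_size),
      Wh1 = rand_mat(2L * spec$hidden_size, spec$dense_units),
      bh1 = rep(0, spec$dense_units),
      Wout = rand_mat(spec$dense_units, 4L), bout = rep(0, 4)
    ),
    cnn = list(
      emb = rand_mat(V, d),
      Wc = rand_mat(spec$kernel_size * d, spec$n_filters),
      bc = rep(0, spec$n_filters),
      Wh1 = rand_mat(spec$n_filters, spec$dense_units),
      bh1 = rep(0, spec$dense_units),
      Wout = rand_mat(spec$dense_units, 4L), bout = rep(0, 4)
    ),
    pretrained_adapter = list(
      Wout = rand_mat(spec$adapter_dim, 4L), bout = rep(0, 4)
    )
  )
}

classifier_fwd <- function(params, spec, ids, text = NULL) {
  if (spec$kind == "pretrained_adapter") {
    feat <- spec$encode_fn(text)
    logits <- drop(feat %*% params$Wout) + params$bout
    return(list(logits = logits, p = softmax_vec(logits), cache = list(feat = feat)))
  }
  T_ <- length(ids)
  if (!T_) stop("empty text")
  X <- params$emb[ids, , drop = FALSE]
  if (spec$kind == "tiny_transformer") {
    pos <- sinusoidal_pos(T_ + 1L, ncol(X))
    X0 <- rbind(params$cls + pos[1L, ],
                X + pos[1L + seq_len(T_), , drop = FALSE])
    fwd <- tf_encoder_fwd(params$enc, spec$n_heads, X0)
    pooled <- fwd$out[1L, ]
    logits <- drop(pooled %*% params$Wout) + params$bout
    cache <- list(ids = ids, fwd = fwd, pooled = pooled)
  } else if (spec$kind == "bilstm") {
    Xr <- X[rev(seq_len(T_)), , drop = FALSE]
    fw <- lstm_fwd(params$fw, X)
    bw <- lstm_fwd(params$bw, Xr)
    feat <- c(fw$h_final, bw$h_final)
    Z1 <- drop(feat %*% params$Wh1) + params$bh1
    h1 <- pmax(Z1, 0)
    logits <- drop(h1 %*% params$Wout) + params$bout
    cache <- list(ids = ids, X = X, Xr = Xr, fw = fw, bw = bw,
                  feat = feat, Z1 = Z1, h1 = h1)
  } else { # cnn
    k <- spec$kernel_size
    Xp <- if (T_ < k) rbind(X, matrix(0, k - T_, ncol(X))) else X
    npos <- nrow(Xp) - k + 1L
    Z <- matrix(0, npos, spec$n_filters)
    for (t in seq_len(npos)) {
      Z[t, ] <- drop(as.numeric(t(Xp[t:(t + k - 1L), , drop = FALSE])) %*% params$Wc) + params$bc
    }
    Rl <- pmax(Z, 0)
    amax <- max.col(t(Rl), ties.method = "first")
    pooled <- Rl[cbind(amax, seq_len(spec$n_filters))]
    Z1 <- drop(pooled %*% params$Wh1) + params$bh1
    h1 <- pmax(Z1, 0)
    logits <- drop(h1 %*% params$Wout) + params$bout
    cache <- list(ids = ids, X = X, Xp = Xp, Z = Z, Rl = Rl, amax = amax,
                  pooled = pooled, Z1 = Z1, h1 = h1, npos = npos)
  }
  list(logits = logits, p = softmax_vec(logits), cache = cache)
}

# returns a gradient tree mirroring init_classifier_params() exactly
classifier_bwd <- function(params, spec, cache, dlogits) {
  if (spec$kind == "pretrained_adapter") {
    return(list(Wout = outer(cache$feat, dlogits), bout = dlogits))
  }
  ids <- cache$ids
  V <- nrow(params$emb)
  d <- ncol(params$emb)
  demb <- matrix(0, V, d)
  if (spec$kind == "tiny_transformer") {
    dWout <- outer(cache$pooled, dlogits)
    dpooled <- drop(params$Wout %*% dlogits)
    dOut <- matrix(0, length(ids) + 1L, d)
    dOut[1L, ] <- dpooled
    gb <- tf_encoder_bwd(params$enc, spec$n_heads, cache$fwd, dOut)
    dX0 <- gb$dX
    for (t in seq_along(ids)) {
      demb[ids[t], ] <- demb[ids[t], ] + dX0[1L + t, ]
    }
    out <- list(emb = demb, cls = dX0[1L, ],
         enc = list(layers = gb$layers, gf = gb$gf, bf = gb$bf),
         Wout = dWout, bout = dlogits)
    attr(out, "dXpos") <- dX0[-1L, , drop = FALSE]
    out
  } else if (spec$kind == "bilstm") {
    dh1 <- drop(params$Wout %*% dlogits)
    dZ1 <- dh1 * (cache$Z1 > 0)
    dfeat <- drop(params$Wh1 %*% dZ1)
    H <- length(cache$fw$h_final)
    gf <- lstm_bwd(params$fw, cache$X, cache$fw, dfeat[seq_len(H)])
    gbk <- lstm_bwd(params$bw, cache$Xr, cache$bw, dfeat[H + seq_len(H)])
    dX <- gf$dX + gbk$dX[rev(seq_len(nrow(gbk$dX))), , drop = FALSE]
    for (t in seq_along(ids)) demb[ids[t], ] <- demb[ids[t], ] + dX[t, ]
    out <- list(emb = demb,
         fw = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
         bw = list(Wx = gbk$dWx, Wh = gbk$dWh, b = gbk$db),
         Wh1 = outer(cache$feat, dZ1), bh1 = dZ1,
         Wout = outer(cache$h1, dlogits), bout = dlogits)
    attr(out, "dXpos") <- dX
    out
  } else { # cnn
    k <- spec$kernel_size
    dh1 <- drop(params$Wout %*% dlogits)
    dZ1 <- dh1 * (cache$Z1 > 0)
    dpooled <- drop(params$Wh1 %*% dZ1)
    dZ <- matrix(0, cache$npos, spec$n_filters)
    for (f in seq_len(spec$n_filters)) {
      t0 <- cache$amax[f]
      dZ[t0, f] <- dpooled[f] * (cache$Z[t0, f] > 0)
    }
    dWc <- matrix(0, nrow(params$Wc), ncol(params$Wc))
    dXp <- matrix(0, nrow(cache$Xp), d)
    for (t in seq_len(cache$npos)) {
      if (all(dZ[t, ] == 0)) next
      win <- as.numeric(t(cache$Xp[t:(t + k - 1L), , drop = FALSE]))
      dWc <- dWc + outer(win, dZ[t, ])
      dwin <- drop(params$Wc %*% dZ[t, ])
      dXp[t:(t + k - 1L), ] <- dXp[t:(t + k - 1L), ] +
        matrix(dwin, k, d, byrow = TRUE)
    }
    for (t in seq_along(ids)) demb[ids[t], ] <- demb[ids[t], ] + dXp[t, ]
    out <- list(emb = demb, Wc = dWc, bc = colSums(dZ),
         Wh1 = outer(cache$pooled, dZ1), bh1 = dZ1,
         Wout = outer(cache$h1, dlogits), bout = dlogits)
    attr(out, "dXpos") <- dXp[seq_along(ids), , drop = FALSE]
    out
  }
}

# ---- training loops ------------------------------------------------------

check_patient_disjoint <- function(train, dev) {
  overlap <- intersect(unique(train$patient_id), unique(dev$patient_id))
  if (length(overlap)) {
    stop("train and dev share patient(s): ", paste(utils::head(overlap, 5), collapse = ", "))
  }
}

train_core <- function(train, dev, spec, config, seed, aug = NULL, w = NULL) {
  train <- validate_corpus(train)
  dev <- validate_corpus(dev)
  check_patient_disjoint(train, dev)
  alpha <- if (is.null(w)) 1 else w$alpha
  beta <- if (is.null(w)) 0 else w$beta
  use_variants <- !is.null(aug) && (beta > 0 || isTRUE(aug$include_variants_in_ce))
  tokenizer <- build_tokenizer(train$conclusion_text, spec$vocab_cap)
  set.seed(as.integer(seed))
  params <- init_classifier_params(spec, vocab_size(tokenizer))
  n <- nrow(train)
  ids_train <- lapply(train$conclusion_text, encode_ids,
                      tokenizer = tokenizer, max_len = spec$max_seq_len)
  y <- label_code(train$label) + 1L
  variants <- NULL
  if (use_variants) {
    variants <- lapply(seq_len(n), function(i) {
      vs <- permute_conclusion(train$conclusion_text[i], P = aug$P,
                               seed = aug$seed + i, max_attempts = aug$max_attempts)
      lapply(vs, function(v) encode_ids(tokenizer, v$text, spec$max_seq_len))
    })
    set.seed(as.integer(seed) + 101L)  # fresh stream for the training loop
  }
  state <- adam_init(params)
  history <- data.frame()
  best_acc <- -Inf
  best_params <- params
  stale <- 0L
  dev_ids <- lapply(dev$conclusion_text, encode_ids,
                    tokenizer = tokenizer, max_len = spec$max_seq_len)
  dev_y <- label_code(dev$label) + 1L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ce_sum <- 0; mse_sum <- 0; mse_n <- 0L
    bstart <- seq(1L, n, by = config$batch_size)
    for (bs in bstart) {
      batch <- ord[bs:min(bs + config$batch_size - 1L, n)]
      gacc <- NULL
      for (i in batch) {
        fo <- classifier_fwd(params, spec, ids_train[[i]], train$conclusion_text[i])
        onehot <- numeric(4); onehot[y[i]] <- 1
        ce <- -log(fo$p[y[i]] + 1e-12)
        dlog_o <- alpha * (fo$p - onehot)
        g <- NULL
        if (use_variants && length(variants[[i]])) {
          vidx <- if (isTRUE(aug$average_all_variants)) seq_along(variants[[i]])
                  else sample.int(length(variants[[i]]), 1L)
          nv <- length(vidx)
          ce_v_sum <- 0
          dlog_o_extra <- numeric(4)
          for (j in vidx) {
            fv <- classifier_fwd(params, spec, variants[[i]][[j]])
            mse <- mean((fo$p - fv$p)^2)
            mse_sum <- mse_sum + mse / nv
            dp <- (2 / 4) * (fo$p - fv$p) * (beta / nv)
            dlog_v <- softmax_vjp(fv$p, -dp)
            if (!isTRUE(aug$stop_gradient_original)) {
              dlog_o_extra <- dlog_o_extra + softmax_vjp(fo$p, dp)
            }
            if (isTRUE(aug$include_variants_in_ce)) {
              ce_v_sum <- ce_v_sum + -log(fv$p[y[i]] + 1e-12) / nv
              dlog_v <- dlog_v + 0.5 * alpha * (fv$p - onehot) / nv
            }
            gv <- classifier_bwd(params, spec, fv$cache, dlog_v)
            g <- if (is.null(g)) gv else tree_add(g, gv)
          }
          mse_n <- mse_n + 1L
          if (isTRUE(aug$include_variants_in_ce)) {
            ce <- 0.5 * ce + 0.5 * ce_v_sum
            dlog_o <- 0.5 * dlog_o
          }
          dlog_o <- dlog_o + dlog_o_extra
        }
        go <- classifier_bwd(params, spec, fo$cache, dlog_o)
        g <- if (is.null(g)) go else tree_add(g, go)
        ce_sum <- ce_sum + ce
        gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
      }
      gacc <- tree_map(function(x) x / length(batch), gacc)
      st <- adam_step(params, gacc, state, config$learning_rate)
      params <- st$params
      state <- st$state
    }
    acc <- mean(vapply(seq_along(dev_ids), function(i) {
      p <- classifier_fwd(params, spec, dev_ids[[i]], dev$conclusion_text[i])$p
      which.max(p) == dev_y[i]
    }, logical(1)))
    ce_ep <- ce_sum / n
    mse_ep <- if (mse_n) mse_sum / mse_n else 0
    history <- rbind(history, data.frame(
      epoch = epoch, ce = ce_ep, mse = mse_ep,
      total = alpha * ce_ep + beta * mse_ep, dev_accuracy = acc))
    if (acc > best_acc) {
      best_acc <- acc
      best_params <- params
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  structure(list(spec = spec, tokenizer = tokenizer, params = best_params,
                 final_params = params, history = history, config = config,
                 seed = seed, aug = aug, weights = list(alpha = alpha, beta = beta),
                 best_dev_accuracy = if (is.finite(best_acc)) best_acc else NA_real_),
            class = "neural_classifier")
}

#' Train a neural classifier with plain cross-entropy
#'
#' Adam on per-batch accumulated gradients; the best-dev-accuracy checkpoint is
#' returned. Training is bit-reproducible given the seed. Train and dev corpora
#' must be patient-disjoint (leakage guard).
#'
#' @param train,dev `response_corpus` objects with disjoint patients.
#' @param spec An [encoder_spec()].
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @return A `neural_classifier` with a per-epoch `history` data frame
#'   (columns epoch, ce, mse, total, dev_accuracy).
#' @export
train_supervised <- function(train, dev, spec = encoder_spec(),
                             config = train_config(), seed = 1L) {
  train_core(train, dev, spec, config, seed, aug = NULL, w = NULL)
}

#' Train a neural classifier with sentence-permutation consistency
#'
#' Each step forwards an original conclusion and one of its P permuted variants
#' (drawn uniformly, or all of them with `average_all_variants`), and minimizes
#' `alpha * CE + beta * MSE(y, y_p)` where the MSE ties the two predicted label
#' distributions together. By default the variants also enter the
#' cross-entropy term as additional labeled samples and the gradient of the
#' consistency term flows through both distributions. With `beta = 0` and
#' `include_variants_in_ce = FALSE` the trajectory reduces exactly to
#' [train_supervised()] under the same seed.
#'
#' @inheritParams train_supervised
#' @param aug An [augmentation_config()].
#' @param w A [consistency_weights()].
#' @return A `neural_classifier`; `history` records the ce and mse components
#'   separately with `total = alpha * ce + beta * mse` at every logged step.
#' @export
train_with_consistency <- function(train, dev, spec = encoder_spec(),
                                   aug = augmentation_config(),
                                   w = consistency_weights(),
                                   config = train_config(), seed = 1L) {
  train_core(train, dev, spec, config, seed, aug = aug, w = w)
}

#' Predicted label distribution for texts
#'
#' @param model A `neural_classifier`.
#' @param texts Character vector (or `response_corpus`).
#' @return Matrix of probabilities (rows sum to 1, columns NED/PR/SD/PD).
#' @export
predict_proba <- function(model, texts) {
  stopifnot(inherits(model, "neural_classifier"))
  if (inherits(texts, "response_corpus")) texts <- texts$conclusion_text
  if (any(!nzchar(trimws(texts)))) stop("empty text")
  P <- t(vapply(texts, function(tx) {
    ids <- encode_ids(model$tokenizer, tx, model$spec$max_seq_len)
    classifier_fwd(model$params, model$spec, ids, tx)$p
  }, numeric(4)))
  dimnames(P) <- list(NULL, response_levels())
  P
}

#' Predict from a neural classifier
#'
#' @param object A `neural_classifier`.
#' @param newdata Character vector of texts or a `response_corpus`.
#' @param type `"class"` (default; argmax with lowest-code tie-break) or
#'   `"prob"`.
#' @param ... Unused.
#' @export
predict.neural_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- predict_proba(object, newdata)
  if (type == "prob") P else argmax_label(P)
}

#' @export
print.neural_classifier <- function(x, ...) {
  cat(sprintf("<neural_classifier> %s, vocab=%d, %d epoch(s), best dev accuracy %.4f\n",
              x$spec$kind, vocab_size(x$tokenizer), nrow(x$history),
              x$best_dev_accuracy))
  invisible(x)
}
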