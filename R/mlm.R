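# Tiny trainable masked language model. Serves as the pluggable PLM behind
# prompt-based fine-tuning: a transformer encoder with a token-level output
# projection over the vocabulary. Any external masked LM honoring the same
# contract (token ids in, per-position vocabulary distributions out) can be
# substituted at production scale.

#' Create a tiny masked language model
#'
#' @param tokenizer A `radr_tokenizer` whose vocabulary must cover the prompt
#'   template and verbalizer phrases (pass them as `extra_texts` to
#'   [build_tokenizer()]).
#' @param embedding_dim,n_layers,n_heads,ff_dim Transformer dimensions
#'   (defaults 32/2/4/64: CPU-scale).
#' @param max_seq_len Maximum sequence length (default 96).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `tiny_mlm`.
#' @export
tiny_mlm <- function(tokenizer, embedding_dim = 32L, n_layers = 2L,
                     n_heads = 4L, ff_dim = 64L, max_seq_len = 96L, seed = 1L) {
  stopifnot(inherits(tokenizer, "radr_tokenizer"))
  if (embedding_dim %% n_heads != 0L) stop("embedding_dim must be divisible by n_heads")
  V <- vocab_size(tokenizer)
  set.seed(as.integer(seed))
  params <- list(
    emb = rand_mat(V, embedding_dim),
    enc = init_tf_encoder(embedding_dim, n_layers, n_heads, ff_dim),
    Wv = rand_mat(embedding_dim, V),
    bv = rep(0, V)
  )
  structure(list(tokenizer = tokenizer, d = embedding_dim, n_layers = n_layers,
                 n_heads = n_heads, ff_dim = ff_dim, max_seq_len = max_seq_len,
                 params = params),
            class = "tiny_mlm")
}

#' @export
print.tiny_mlm <- function(x, ...) {
  cat(sprintf("<tiny_mlm> d=%d, %d layer(s), %d head(s), vocab=%d\n",
              x$d, x$n_layers, x$n_heads, vocab_size(x$tokenizer)))
  invisible(x)
}

mlm_fwd <- function(mlm, ids) {
  T_ <- length(ids)
  if (T_ > mlm$max_seq_len) stop("sequence exceeds max_seq_len")
  X0 <- mlm$params$emb[ids, , drop = FALSE] +
    sinusoidal_pos(T_, mlm$d)
  enc <- tf_encoder_fwd(mlm$params$enc, mlm$n_heads, X0)
  logits <- enc$out %*% mlm$params$Wv +
    matrix(mlm$params$bv, T_, length(mlm$params$bv), byrow = TRUE)
  list(logits = logits, probs = softmax_rows(logits), enc = enc, ids = ids)
}

# gradient tree mirroring the tiny_mlm params tree
mlm_bwd <- function(mlm, fwd, dLogits) {
  ids <- fwd$ids
  dWv <- crossprod(fwd$enc$out, dLogits)
  dbv <- colSums(dLogits)
  dOut <- dLogits %*% t(mlm$params$Wv)
  gb <- tf_encoder_bwd(mlm$params$enc, mlm$n_heads, fwd$enc, dOut)
  demb <- matrix(0, nrow(mlm$params$emb), mlm$d)
  for (t in seq_along(ids)) {
    demb[ids[t], ] <- demb[ids[t], ] + gb$dX[t, ]
  }
  list(emb = demb,
       enc = list(layers = gb$layers, gf = gb$gf, bf = gb$bf),
       Wv = dWv, bv = dbv)
}

#' Pre-train a tiny masked LM on unlabeled conclusions
#'
#' Standard masked-token objective: at each step one text is sampled, a
#' fraction `mask_ratio` of its tokens (at least one) is replaced by the mask
#' token, and the model is trained with cross-entropy to restore the original
#' tokens at the masked positions.
#'
#' @param mlm A `tiny_mlm`.
#' @param texts Character vector of unlabeled texts (or a `response_corpus`).
#' @param steps Number of gradient steps.
#' @param mask_ratio Masking probability per token (default 0.15).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed.
#' @return The updated `tiny_mlm`, with a `pretrain_loss` attribute (mean
#'   masked-token cross-entropy per 50-step window).
#' @export
pretrain_mlm <- function(mlm, texts, steps = 500L, mask_ratio = 0.15,
                         learning_rate = 1e-3, seed = 1L) {
  stopifnot(inherits(mlm, "tiny_mlm"))
  if (inherits(texts, "response_corpus")) texts <- texts$conclusion_text
  ids_all <- lapply(texts, encode_ids, tokenizer = mlm$tokenizer,
                    max_len = mlm$max_seq_len)
  ids_all <- ids_all[lengths(ids_all) >= 2L]
  if (!length(ids_all)) stop("no usable texts")
  set.seed(as.integer(seed))
  state <- adam_init(mlm$params)
  losses <- numeric(0)
  for (s in seq_len(steps)) {
    ids <- ids_all[[sample.int(length(ids_all), 1L)]]
    maskpos <- which(stats::runif(length(ids)) < mask_ratio)
    if (!length(maskpos)) maskpos <- sample.int(length(ids), 1L)
    corrupted <- ids
    corrupted[maskpos] <- MASK_ID
    fwd <- mlm_fwd(mlm, corrupted)
    dLogits <- matrix(0, length(ids), ncol(fwd$logits))
    loss <- 0
    for (mp in maskpos) {
      p <- fwd$probs[mp, ]
      tgt <- ids[mp]
      loss <- loss - log(p[tgt] + 1e-12)
      dp <- p
      dp[tgt] <- dp[tgt] - 1
      dLogits[mp, ] <- dp / length(maskpos)
    }
    losses <- c(losses, loss / length(maskpos))
    g <- mlm_bwd(mlm, fwd, dLogits)
    st <- adam_step(mlm$params, g, state, learning_rate)
    mlm$params <- st$params
    state <- st$state
  }
  attr(mlm, "pretrain_loss") <- losses
  mlm
}
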