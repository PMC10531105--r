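# Numerical core for the small neural classifiers and the tiny masked LM.
#
# Everything is plain R matrix algebra with hand-derived reverse-mode
# gradients, processed one sequence at a time (sequences are short conclusion
# texts, so there is no padding inside the math: masking contracts hold
# trivially). Gradients are verified against central finite differences in the
# test suite.

.ln_eps <- 1e-5

rand_mat <- function(nr, nc, scale = 0.08) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# VJP of p = softmax(z): given dL/dp, return dL/dz = p * (dp - sum(dp * p))
softmax_vjp <- function(p, dp) p * (dp - sum(dp * p))

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + .ln_eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2L, g, "*") + matrix(b, nrow(X), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dY) {
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  list(dX = (dxhat - m1 - cache$xhat * m2) * cache$inv,
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

# ---- transformer encoder ------------------------------------------------

# fixed sinusoidal positional encodings (standard transformer recipe); these
# make token order visible to the encoder without adding trainable state
sinusoidal_pos <- function(max_len, d) {
  pos <- matrix(0, max_len, d)
  t <- seq_len(max_len)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2L * i - 1L] <- sin(t * freq)
    if (2L * i <= d) pos[, 2L * i] <- cos(t * freq)
  }
  pos
}

init_tf_layer <- function(d, ff_dim) {
  list(g1 = rep(1, d), b1 = rep(0, d),
       Wq = rand_mat(d, d), Wk = rand_mat(d, d), Wv = rand_mat(d, d),
       Wo = rand_mat(d, d),
       g2 = rep(1, d), b2 = rep(0, d),
       W1 = rand_mat(d, ff_dim), bf1 = rep(0, ff_dim),
       W2 = rand_mat(ff_dim, d), bf2 = rep(0, d))
}

# the returned tree holds parameters only; n_heads travels in the model spec
init_tf_encoder <- function(d, n_layers, n_heads, ff_dim) {
  stopifnot(d %% n_heads == 0L)
  list(layers = lapply(seq_len(n_layers), function(i) init_tf_layer(d, ff_dim)),
       gf = rep(1, d), bf = rep(0, d))
}

attn_fwd <- function(H, lp, n_heads) {
  d <- ncol(H)
  dh <- d %/% n_heads
  Q <- H %*% lp$Wq; K <- H %*% lp$Wk; V <- H %*% lp$Wv
  O <- matrix(0, nrow(H), d)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  list(out = O %*% lp$Wo, Q = Q, K = K, V = V, O = O, A = A_list)
}

attn_bwd <- function(H, lp, n_heads, cache, dOut) {
  d <- ncol(H)
  dh <- d %/% n_heads
  dWo <- crossprod(cache$O, dOut)
  dOc <- dOut %*% t(lp$Wo)
  dQ <- matrix(0, nrow(H), d); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dOh <- dOc[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dV[, idx] <- crossprod(A, dOh)
    dA <- dOh %*% t(Vh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  list(dH = dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv),
       dWq = crossprod(H, dQ), dWk = crossprod(H, dK), dWv = crossprod(H, dV),
       dWo = dWo)
}

tf_encoder_fwd <- function(enc, n_heads, X) {
  caches <- vector("list", length(enc$layers))
  for (l in seq_along(enc$layers)) {
    lp <- enc$layers[[l]]
    ln1 <- layernorm_fwd(X, lp$g1, lp$b1)
    at <- attn_fwd(ln1$out, lp, n_heads)
    X2 <- X + at$out
    ln2 <- layernorm_fwd(X2, lp$g2, lp$b2)
    Z1 <- ln2$out %*% lp$W1 + matrix(lp$bf1, nrow(X), length(lp$bf1), byrow = TRUE)
    R <- pmax(Z1, 0)
    FF <- R %*% lp$W2 + matrix(lp$bf2, nrow(X), length(lp$bf2), byrow = TRUE)
    X3 <- X2 + FF
    caches[[l]] <- list(X = X, ln1 = ln1, at = at, X2 = X2, ln2 = ln2,
                        Z1 = Z1, R = R)
    X <- X3
  }
  lnf <- layernorm_fwd(X, enc$gf, enc$bf)
  list(out = lnf$out, lnf = lnf, X_last = X, caches = caches)
}

tf_encoder_bwd <- function(enc, n_heads, fwd, dOut) {
  g <- list(layers = vector("list", length(enc$layers)))
  lnb <- layernorm_bwd(fwd$lnf, enc$gf, dOut)
  g$gf <- lnb$dg; g$bf <- lnb$db
  dX3 <- lnb$dX
  for (l in rev(seq_along(enc$layers))) {
    lp <- enc$layers[[l]]
    cc <- fwd$caches[[l]]
    # FFN branch
    dFF <- dX3
    dR <- dFF %*% t(lp$W2)
    dW2 <- crossprod(cc$R, dFF); dbf2 <- colSums(dFF)
    dZ1 <- dR * (cc$Z1 > 0)
    dW1 <- crossprod(cc$ln2$out, dZ1); dbf1 <- colSums(dZ1)
    dln2out <- dZ1 %*% t(lp$W1)
    ln2b <- layernorm_bwd(cc$ln2, lp$g2, dln2out)
    dX2 <- dX3 + ln2b$dX
    # attention branch
    ab <- attn_bwd(cc$ln1$out, lp, n_heads, cc$at, dX2)
    ln1b <- layernorm_bwd(cc$ln1, lp$g1, ab$dH)
    dX <- dX2 + ln1b$dX
    g$layers[[l]] <- list(g1 = ln1b$dg, b1 = ln1b$db,
                          Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv, Wo = ab$dWo,
                          g2 = ln2b$dg, b2 = ln2b$db,
                          W1 = dW1, bf1 = dbf1, W2 = dW2, bf2 = dbf2)
    dX3 <- dX
  }
  g$dX <- dX3
  g
}

# ---- LSTM ----------------------------------------------------------------

init_lstm <- function(d, H) {
  list(Wx = rand_mat(d, 4L * H), Wh = rand_mat(H, 4L * H), b = rep(0, 4L * H))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_fwd <- function(lstm, X) {
  H <- nrow(lstm$Wh)
  T_ <- nrow(X)
  h <- rep(0, H); c_ <- rep(0, H)
  cache <- vector("list", T_)
  hs <- matrix(0, T_, H)
  for (t in seq_len(T_)) {
    z <- drop(X[t, ] %*% lstm$Wx) + drop(h %*% lstm$Wh) + lstm$b
    i <- sigmoid(z[1:H]); f <- sigmoid(z[(H + 1):(2 * H)])
    o <- sigmoid(z[(2 * H + 1):(3 * H)]); g <- tanh(z[(3 * H + 1):(4 * H)])
    c_new <- f * c_ + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(x = X[t, ], h_prev = h, c_prev = c_, i = i, f = f,
                       o = o, g = g, tc = tc)
    h <- h_new; c_ <- c_new
    hs[t, ] <- h
  }
  list(h_final = h, hs = hs, cache = cache)
}

# dh_final: gradient wrt final hidden state; dhs: optional T x H matrix of
# per-step gradients (for pooled usage). Returns grads and dX.
lstm_bwd <- function(lstm, X, fwd, dh_final, dhs = NULL) {
  H <- nrow(lstm$Wh)
  T_ <- nrow(X)
  dWx <- matrix(0, nrow(lstm$Wx), ncol(lstm$Wx))
  dWh <- matrix(0, nrow(lstm$Wh), ncol(lstm$Wh))
  db <- rep(0, 4L * H)
  dX <- matrix(0, T_, ncol(X))
  dh <- dh_final
  dc <- rep(0, H)
  for (t in rev(seq_len(T_))) {
    if (!is.null(dhs)) dh <- dh + dhs[t, ]
    cc <- fwd$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$c_prev
    dc_prev <- dc * cc$f
    dz <- c(di * cc$i * (1 - cc$i),
            df * cc$f * (1 - cc$f),
            do_ * cc$o * (1 - cc$o),
            dg * (1 - cc$g^2))
    dWx <- dWx + outer(cc$x, dz)
    dWh <- dWh + outer(cc$h_prev, dz)
    db <- db + dz
    dX[t, ] <- drop(lstm$Wx %*% dz)
    dh <- drop(lstm$Wh %*% dz)
    dc <- dc_prev
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# ---- parameter-tree utilities -------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

tree_add <- function(a, b) tree_map2(`+`, a, b)

# Adam step on a numeric parameter tree; state holds m, v, t.
adam_init <- function(params) list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
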