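# Internal neural-network primitives: explicit forward/backward passes in
# base R matrix code, and an AdamW optimizer over flat named parameter lists.
# The encoder is a pre-normalization transformer (LN -> multi-head
# self-attention -> residual; LN -> GELU feed-forward -> residual) with a
# final layer norm. No positional information enters anywhere: the forward
# pass consumes token ids only, so per-token outputs are exactly
# permutation-equivariant.

LN_EPS <- 1e-5

add_bias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(Y = add_bias(sweep(xhat, 2L, g, "*"), b), xhat = xhat, inv = inv, g = g)
}

ln_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, cache$g, "*")
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

pn <- function(l, nm) sprintf("l%d.%s", l, nm)

# ---- parameter initialization -------------------------------------------

init_encoder_params <- function(cfg, seed = 0L) {
  with_local_seed(seed, {
    d <- cfg$d_model; f <- cfg$ffn_dim; V <- cfg$vocab_size
    rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    p <- list()
    p[["E"]] <- rmat(V + 1L, d)  # last row: reserved PAD id (= V, 0-based)
    for (l in seq_len(cfg$n_layers)) {
      p[[pn(l, "ln1_g")]] <- rep(1, d); p[[pn(l, "ln1_b")]] <- rep(0, d)
      for (w in c("Wq", "Wk", "Wv", "Wo")) p[[pn(l, w)]] <- rmat(d, d)
      for (b in c("bq", "bk", "bv", "bo")) p[[pn(l, b)]] <- rep(0, d)
      p[[pn(l, "ln2_g")]] <- rep(1, d); p[[pn(l, "ln2_b")]] <- rep(0, d)
      p[[pn(l, "W1")]] <- rmat(d, f); p[[pn(l, "b1")]] <- rep(0, f)
      p[[pn(l, "W2")]] <- rmat(f, d); p[[pn(l, "b2")]] <- rep(0, d)
    }
    p[["lnf_g"]] <- rep(1, d); p[["lnf_b"]] <- rep(0, d)
    # zero-initialized head: an untrained model predicts exactly 0.5 everywhere
    p[["rtd_w"]] <- rep(0, d); p[["rtd_b"]] <- 0
    p
  })
}

# ---- transformer forward / backward -------------------------------------

# token_list: list of 0-based integer id vectors (ragged batch; empty cells
# contribute no rows, which realizes the "padding carries no gradient and is
# excluded from pooling/loss" contract without materializing PAD positions).
transformer_forward <- function(params, cfg, token_list, train = FALSE,
                                want_cache = FALSE) {
  lens <- vapply(token_list, length, integer(1L))
  N <- sum(lens)
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  rows <- split(seq_len(N), rep(seq_along(token_list), lens))
  rows_full <- stats::setNames(vector("list", length(token_list)),
                               as.character(seq_along(token_list)))
  rows_full[names(rows)] <- rows
  ids <- unlist(token_list, use.names = FALSE)
  if (length(ids) && any(ids < 0L | ids >= cfg$vocab_size)) {
    stop("transformer_forward: token id out of range [0, V)", call. = FALSE)
  }
  drop_rate <- if (train) cfg$dropout else 0
  X <- params$E[ids + 1L, , drop = FALSE]
  cache <- if (want_cache) list(layers = vector("list", cfg$n_layers)) else NULL
  head_cols <- lapply(seq_len(nh), function(h) ((h - 1L) * dh + 1L):(h * dh))
  for (l in seq_len(cfg$n_layers)) {
    ln1 <- ln_fwd(X, params[[pn(l, "ln1_g")]], params[[pn(l, "ln1_b")]])
    N1 <- ln1$Y
    Q <- add_bias(N1 %*% params[[pn(l, "Wq")]], params[[pn(l, "bq")]])
    K <- add_bias(N1 %*% params[[pn(l, "Wk")]], params[[pn(l, "bk")]])
    Vv <- add_bias(N1 %*% params[[pn(l, "Wv")]], params[[pn(l, "bv")]])
    O <- matrix(0, N, d)
    A_cache <- if (want_cache) vector("list", length(rows_full)) else NULL
    for (ci in seq_along(rows_full)) {
      idx <- rows_full[[ci]]
      if (length(idx) == 0L) next
      Ac <- if (want_cache) vector("list", nh) else NULL
      for (h in seq_len(nh)) {
        cols <- head_cols[[h]]
        S <- tcrossprod(Q[idx, cols, drop = FALSE], K[idx, cols, drop = FALSE]) / sqrt(dh)
        A <- softmax_rows(S)
        O[idx, cols] <- A %*% Vv[idx, cols, drop = FALSE]
        if (want_cache) Ac[[h]] <- A
      }
      if (want_cache) A_cache[[ci]] <- Ac
    }
    attn_out <- add_bias(O %*% params[[pn(l, "Wo")]], params[[pn(l, "bo")]])
    mask1 <- NULL
    if (drop_rate > 0) {
      mask1 <- matrix((stats::runif(N * d) >= drop_rate) / (1 - drop_rate), N, d)
      attn_out <- attn_out * mask1
    }
    X_mid <- X + attn_out
    ln2 <- ln_fwd(X_mid, params[[pn(l, "ln2_g")]], params[[pn(l, "ln2_b")]])
    Z1 <- add_bias(ln2$Y %*% params[[pn(l, "W1")]], params[[pn(l, "b1")]])
    G <- gelu(Z1)
    ffn_out <- add_bias(G %*% params[[pn(l, "W2")]], params[[pn(l, "b2")]])
    mask2 <- NULL
    if (drop_rate > 0) {
      mask2 <- matrix((stats::runif(N * cfg$ffn_dim) >= drop_rate) / (1 - drop_rate),
                      N, cfg$ffn_dim)
      # dropout on the hidden activation keeps the mask shape simple
      ffn_out <- add_bias((G * mask2) %*% params[[pn(l, "W2")]], params[[pn(l, "b2")]])
    }
    X_new <- X_mid + ffn_out
    if (want_cache) {
      cache$layers[[l]] <- list(ln1 = ln1, N1 = N1, Q = Q, K = K, V = Vv,
                                A = A_cache, O = O, mask1 = mask1,
                                X_mid = X_mid, ln2 = ln2, Z1 = Z1, G = G,
                                mask2 = mask2)
    }
    X <- X_new
  }
  lnf <- ln_fwd(X, params$lnf_g, params$lnf_b)
  if (want_cache) cache$lnf <- lnf
  list(H = lnf$Y, rows = rows_full, lens = lens, ids = ids, cache = cache,
       head_cols = head_cols)
}

transformer_backward <- function(params, cfg, fw, dH) {
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  N <- nrow(dH)
  g <- list()
  bl <- ln_bwd(dH, fw$cache$lnf)
  g[["lnf_g"]] <- bl$dg; g[["lnf_b"]] <- bl$db
  dX <- bl$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    cc <- fw$cache$layers[[l]]
    # feed-forward branch
    dffn <- dX
    if (!is.null(cc$mask2)) {
      dGm <- (dffn %*% t(params[[pn(l, "W2")]]))
      g[[pn(l, "W2")]] <- crossprod(cc$G * cc$mask2, dffn)
      dG <- dGm * cc$mask2
    } else {
      g[[pn(l, "W2")]] <- crossprod(cc$G, dffn)
      dG <- dffn %*% t(params[[pn(l, "W2")]])
    }
    g[[pn(l, "b2")]] <- colSums(dffn)
    dZ1 <- dG * gelu_grad(cc$Z1)
    g[[pn(l, "W1")]] <- crossprod(cc$ln2$Y, dZ1)
    g[[pn(l, "b1")]] <- colSums(dZ1)
    dN2 <- dZ1 %*% t(params[[pn(l, "W1")]])
    bl2 <- ln_bwd(dN2, cc$ln2)
    g[[pn(l, "ln2_g")]] <- bl2$dg; g[[pn(l, "ln2_b")]] <- bl2$db
    dX_mid <- dX + bl2$dX
    # attention branch
    dattn <- dX_mid
    if (!is.null(cc$mask1)) dattn <- dattn * cc$mask1
    g[[pn(l, "Wo")]] <- crossprod(cc$O, dattn)
    g[[pn(l, "bo")]] <- colSums(dattn)
    dO <- dattn %*% t(params[[pn(l, "Wo")]])
    dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (ci in seq_along(fw$rows)) {
      idx <- fw$rows[[ci]]
      if (length(idx) == 0L) next
      for (h in seq_len(nh)) {
        cols <- fw$head_cols[[h]]
        A <- cc$A[[ci]][[h]]
        dOh <- dO[idx, cols, drop = FALSE]
        Vh <- cc$V[idx, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[idx, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[idx, cols] <- dS %*% cc$K[idx, cols, drop = FALSE] / sqrt(dh)
        dK[idx, cols] <- crossprod(dS, cc$Q[idx, cols, drop = FALSE]) / sqrt(dh)
      }
    }
    g[[pn(l, "Wq")]] <- crossprod(cc$N1, dQ); g[[pn(l, "bq")]] <- colSums(dQ)
    g[[pn(l, "Wk")]] <- crossprod(cc$N1, dK); g[[pn(l, "bk")]] <- colSums(dK)
    g[[pn(l, "Wv")]] <- crossprod(cc$N1, dV); g[[pn(l, "bv")]] <- colSums(dV)
    dN1 <- dQ %*% t(params[[pn(l, "Wq")]]) +
      dK %*% t(params[[pn(l, "Wk")]]) +
      dV %*% t(params[[pn(l, "Wv")]])
    bl1 <- ln_bwd(dN1, cc$ln1)
    g[[pn(l, "ln1_g")]] <- bl1$dg; g[[pn(l, "ln1_b")]] <- bl1$db
    dX <- dX_mid + bl1$dX
  }
  gE <- matrix(0, cfg$vocab_size + 1L, d)
  if (N > 0L) {
    rs <- rowsum(dX, fw$ids)
    gE[as.integer(rownames(rs)) + 1L, ] <- rs
  }
  g[["E"]] <- gE
  g
}

# ---- small dense nets (RNA encoder / decoder towers) ---------------------

init_mlp_params <- function(dims, seed = 0L, prefix = "fc") {
  with_local_seed(seed, {
    p <- list()
    for (i in seq_len(length(dims) - 1L)) {
      sd <- sqrt(2 / dims[i])
      p[[sprintf("%s%d.W", prefix, i)]] <-
        matrix(stats::rnorm(dims[i] * dims[i + 1L], sd = sd), dims[i], dims[i + 1L])
      p[[sprintf("%s%d.b", prefix, i)]] <- rep(0, dims[i + 1L])
    }
    p
  })
}

# forward through stacked dense layers with ReLU between (linear final layer)
mlp_forward <- function(params, X, n_layers, prefix = "fc", want_cache = FALSE) {
  cache <- list()
  A <- X
  for (i in seq_len(n_layers)) {
    Z <- add_bias(A %*% params[[sprintf("%s%d.W", prefix, i)]],
                  params[[sprintf("%s%d.b", prefix, i)]])
    if (want_cache) cache[[i]] <- list(A_in = A, Z = Z)
    A <- if (i < n_layers) pmax(Z, 0) else Z
  }
  list(Y = A, cache = cache)
}

mlp_backward <- function(params, fw, dY, n_layers, prefix = "fc") {
  g <- list()
  dA <- dY
  for (i in rev(seq_len(n_layers))) {
    cc <- fw$cache[[i]]
    dZ <- if (i < n_layers) dA * (cc$Z > 0) else dA
    g[[sprintf("%s%d.W", prefix, i)]] <- crossprod(cc$A_in, dZ)
    g[[sprintf("%s%d.b", prefix, i)]] <- colSums(dZ)
    dA <- dZ %*% t(params[[sprintf("%s%d.W", prefix, i)]])
  }
  g$dX <- dA
  g
}

# ---- AdamW ---------------------------------------------------------------

adamw_init <- function(params) {
  zero_like <- lapply(params, function(p) p * 0)
  list(m = zero_like, v = zero_like, t = 0L)
}

# weight decay is decoupled (AdamW) and applied to 2-D weight matrices only
# (not biases, layer-norm scales, or the embedding table)
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.matrix(params[[nm]]) && nm != "E" && weight_decay > 0) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
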