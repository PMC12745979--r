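# Scaled-down encoder-decoder transformer (original architecture: sinusoidal
# positional encoding, multi-head attention, post-layer-norm residual
# blocks, ReLU feed-forward), implemented as base R matrix code with
# hand-derived backpropagation. Row-wise operations (projections,
# layer norm, feed-forward) run on the whole minibatch stacked into one
# matrix; attention runs per sample (sequences are ragged, no padding is
# ever materialized inside the model).

.LN_EPS <- 1e-5

# ---- parameter tree ---------------------------------------------------

.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

.init_attn <- function(d) {
  # no projection biases: they are redundant under layer norm and double
  # the allocation traffic of the hot path
  list(Wq = .glorot(d, d), Wk = .glorot(d, d),
       Wv = .glorot(d, d), Wo = .glorot(d, d))
}

.init_ln <- function(d) list(g = rep(1, d), b = numeric(d))

.init_ff <- function(d, dff) {
  list(W1 = .glorot(d, dff), b1 = numeric(dff),
       W2 = .glorot(dff, d), b2 = numeric(d))
}

.init_params <- function(cfg, v_src, v_tgt) {
  d <- cfg$d_model
  list(
    src_emb = .glorot(v_src, d),
    tgt_emb = .glorot(v_tgt, d),
    enc = lapply(seq_len(cfg$n_encoder_layers), function(i)
      list(attn = .init_attn(d), ln1 = .init_ln(d),
           ff = .init_ff(d, cfg$d_ff), ln2 = .init_ln(d))),
    dec = lapply(seq_len(cfg$n_decoder_layers), function(i)
      list(self_attn = .init_attn(d), ln1 = .init_ln(d),
           cross_attn = .init_attn(d), ln2 = .init_ln(d),
           ff = .init_ff(d, cfg$d_ff), ln3 = .init_ln(d))),
    # zero-initialized output head: the initial predictive distribution is
    # exactly uniform (per-token loss ln V), a useful sanity anchor
    out = list(W = matrix(0, d, v_tgt), b = numeric(v_tgt))
  )
}

.tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    key <- function(i) if (!is.null(names(a)) && nzchar(names(a)[i])) names(a)[i] else i
    out <- if (is.null(b)) lapply(seq_along(a), function(i) .tree_map(f, a[[i]]))
           else lapply(seq_along(a), function(i) .tree_map(f, a[[i]], b[[key(i)]]))
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

.zero_like <- function(tree) .tree_map(function(x) x * 0, tree)

# ---- primitive layers -------------------------------------------------

.addb <- function(Y, b) Y + matrix(b, nrow(Y), length(b), byrow = TRUE)

.linear_fwd <- function(X, W, b) .addb(X %*% W, b)

.ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .LN_EPS)
  xhat <- xc * inv
  list(Y = .addb(xhat * matrix(g, nrow(X), length(g), byrow = TRUE), b),
       xhat = xhat, inv = inv)
}

.ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dY); d <- ncol(dY)
  dxhat <- dY * matrix(g, n, d, byrow = TRUE)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

.softmax_rows <- function(S) {
  if (ncol(S) == 1) return(matrix(1, nrow(S), 1))
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# Multi-head attention over a ragged batch. Xq/Xkv are stacked matrices;
# qoff/koff give 0-based row offsets, qlen/klen per-sample lengths.
.mha_fwd <- function(p, cfg, Xq, Xkv, qoff, qlen, koff, klen, causal) {
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d %/% H
  Q <- Xq %*% p$Wq
  K <- Xkv %*% p$Wk
  V <- Xkv %*% p$Wv
  C <- matrix(0, nrow(Xq), d)
  P_cache <- vector("list", length(qlen))
  scale <- 1 / sqrt(dh)
  for (i in seq_along(qlen)) {
    qi <- qoff[i] + seq_len(qlen[i]); ki <- koff[i] + seq_len(klen[i])
    Pi <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- (h - 1) * dh + seq_len(dh)
      S <- (Q[qi, cols, drop = FALSE] %*% t(K[ki, cols, drop = FALSE])) * scale
      if (causal) S[upper.tri(S)] <- -Inf
      P <- .softmax_rows(S)
      Pi[[h]] <- P
      C[qi, cols] <- P %*% V[ki, cols, drop = FALSE]
    }
    P_cache[[i]] <- Pi
  }
  Out <- C %*% p$Wo
  list(Out = Out, Q = Q, K = K, V = V, C = C, P = P_cache)
}

.mha_bwd <- function(dOut, p, cfg, cache, Xq, Xkv, qoff, qlen, koff, klen) {
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d %/% H
  scale <- 1 / sqrt(dh)
  dC <- dOut %*% t(p$Wo)
  dQ <- matrix(0, nrow(Xq), d); dK <- matrix(0, nrow(Xkv), d); dV <- dK
  for (i in seq_along(qlen)) {
    qi <- qoff[i] + seq_len(qlen[i]); ki <- koff[i] + seq_len(klen[i])
    for (h in seq_len(H)) {
      cols <- (h - 1) * dh + seq_len(dh)
      P <- cache$P[[i]][[h]]
      dCh <- dC[qi, cols, drop = FALSE]
      Vh <- cache$V[ki, cols, drop = FALSE]
      dP <- dCh %*% t(Vh)
      dV[ki, cols] <- dV[ki, cols] + t(P) %*% dCh
      dS <- P * (dP - rowSums(dP * P))
      dQ[qi, cols] <- dQ[qi, cols] +
        (dS %*% cache$K[ki, cols, drop = FALSE]) * scale
      dK[ki, cols] <- dK[ki, cols] +
        (t(dS) %*% cache$Q[qi, cols, drop = FALSE]) * scale
    }
  }
  # same element order as .init_attn so gradient and parameter trees align
  g <- list(Wq = t(Xq) %*% dQ, Wk = t(Xkv) %*% dK,
            Wv = t(Xkv) %*% dV, Wo = t(cache$C) %*% dOut)
  list(g = g,
       dXq = dQ %*% t(p$Wq),
       dXkv = dK %*% t(p$Wk) + dV %*% t(p$Wv))
}

.ff_fwd <- function(p, X) {
  Hpre <- .linear_fwd(X, p$W1, p$b1)
  Hact <- Hpre * (Hpre > 0)
  list(Y = .linear_fwd(Hact, p$W2, p$b2), Hpre = Hpre, Hact = Hact)
}

.ff_bwd <- function(dY, p, cache, X) {
  dH <- (dY %*% t(p$W2)) * (cache$Hpre > 0)
  list(g = list(W1 = t(X) %*% dH, b1 = colSums(dH),
                W2 = t(cache$Hact) %*% dY, b2 = colSums(dY)),
       dX = dH %*% t(p$W1))
}

.dropout_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(dim1 * dim2) >= rate) / (1 - rate), dim1, dim2)
}

.apply_drop <- function(X, mask) if (is.null(mask)) X else X * mask

# ---- batch assembly ---------------------------------------------------

# batch: list(src = list of integer id vectors, tgt = list of integer id
# vectors including [start]...[end], no padding)
.stack_batch <- function(ids_list) {
  len <- lengths(ids_list)
  list(ids = as.integer(unlist(ids_list)), len = len,
       off = as.integer(cumsum(c(0L, len[-length(len)]))))
}

.embed <- function(emb, ids, off, len, d) {
  X <- emb[ids, , drop = FALSE] * sqrt(d)
  pos <- unlist(lapply(len, function(l) seq_len(l) - 1))
  X + positional_encoding(pos, d)
}

# ---- full forward / backward ------------------------------------------

.forward_batch <- function(params, cfg, src, tgt_in, tgt_out, dropout = 0) {
  d <- cfg$d_model
  cache <- list(src = src, tgt_in = tgt_in, tgt_out = tgt_out)

  X <- .embed(params$src_emb, src$ids, src$off, src$len, d)
  cache$drop_src <- .dropout_mask(nrow(X), d, dropout)
  X <- .apply_drop(X, cache$drop_src)
  cache$enc_in <- list(); cache$enc <- list()
  for (l in seq_along(params$enc)) {
    p <- params$enc[[l]]; lc <- list(X_in = X)
    a <- .mha_fwd(p$attn, cfg, X, X, src$off, src$len, src$off, src$len, causal = FALSE)
    lc$attn <- a
    lc$drop1 <- .dropout_mask(nrow(X), d, dropout)
    R1 <- X + .apply_drop(a$Out, lc$drop1)
    n1 <- .ln_fwd(R1, p$ln1$g, p$ln1$b); lc$ln1 <- n1
    f <- .ff_fwd(p$ff, n1$Y); lc$ff <- f
    lc$drop2 <- .dropout_mask(nrow(X), d, dropout)
    R2 <- n1$Y + .apply_drop(f$Y, lc$drop2)
    n2 <- .ln_fwd(R2, p$ln2$g, p$ln2$b); lc$ln2 <- n2
    X <- n2$Y
    cache$enc[[l]] <- lc
  }
  memory <- X

  Y <- .embed(params$tgt_emb, tgt_in$ids, tgt_in$off, tgt_in$len, d)
  cache$drop_tgt <- .dropout_mask(nrow(Y), d, dropout)
  Y <- .apply_drop(Y, cache$drop_tgt)
  cache$dec <- list()
  for (l in seq_along(params$dec)) {
    p <- params$dec[[l]]; lc <- list(Y_in = Y)
    a1 <- .mha_fwd(p$self_attn, cfg, Y, Y, tgt_in$off, tgt_in$len,
                   tgt_in$off, tgt_in$len, causal = TRUE)
    lc$self <- a1
    lc$drop1 <- .dropout_mask(nrow(Y), d, dropout)
    R1 <- Y + .apply_drop(a1$Out, lc$drop1)
    n1 <- .ln_fwd(R1, p$ln1$g, p$ln1$b); lc$ln1 <- n1
    a2 <- .mha_fwd(p$cross_attn, cfg, n1$Y, memory, tgt_in$off, tgt_in$len,
                   src$off, src$len, causal = FALSE)
    lc$cross <- a2
    lc$drop2 <- .dropout_mask(nrow(Y), d, dropout)
    R2 <- n1$Y + .apply_drop(a2$Out, lc$drop2)
    n2 <- .ln_fwd(R2, p$ln2$g, p$ln2$b); lc$ln2 <- n2
    f <- .ff_fwd(p$ff, n2$Y); lc$ff <- f
    lc$drop3 <- .dropout_mask(nrow(Y), d, dropout)
    R3 <- n2$Y + .apply_drop(f$Y, lc$drop3)
    n3 <- .ln_fwd(R3, p$ln3$g, p$ln3$b); lc$ln3 <- n3
    Y <- n3$Y
    cache$dec[[l]] <- lc
  }

  logits <- .linear_fwd(Y, params$out$W, params$out$b)
  mx <- logits[cbind(seq_len(nrow(logits)), max.col(logits, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(logits - mx)))
  picked <- logits[cbind(seq_len(nrow(logits)), tgt_out$ids)]
  n_tok <- length(tgt_out$ids)
  loss <- sum(lse - picked) / n_tok
  cache$memory <- memory; cache$Ydec <- Y; cache$logits <- logits; cache$lse <- lse
  list(loss = loss, n_tokens = n_tok, cache = cache)
}

.backward_batch <- function(params, cfg, fw) {
  cache <- fw$cache
  src <- cache$src; tgt_in <- cache$tgt_in; tgt_out <- cache$tgt_out
  d <- cfg$d_model
  grads <- .zero_like(params)

  P <- exp(cache$logits - cache$lse)   # softmax rows
  P[cbind(seq_len(nrow(P)), tgt_out$ids)] <-
    P[cbind(seq_len(nrow(P)), tgt_out$ids)] - 1
  dlogits <- P / fw$n_tokens
  grads$out$W <- t(cache$Ydec) %*% dlogits
  grads$out$b <- colSums(dlogits)
  dY <- dlogits %*% t(params$out$W)
  dMem <- matrix(0, nrow(cache$memory), d)

  for (l in rev(seq_along(params$dec))) {
    p <- params$dec[[l]]; lc <- cache$dec[[l]]
    b3 <- .ln_bwd(dY, lc$ln3, p$ln3$g)
    grads$dec[[l]]$ln3$g <- b3$dg; grads$dec[[l]]$ln3$b <- b3$db
    dR3 <- b3$dX
    dF <- .apply_drop(dR3, lc$drop3)
    fb <- .ff_bwd(dF, p$ff, lc$ff, lc$ln2$Y)
    grads$dec[[l]]$ff <- fb$g
    dN2 <- dR3 + fb$dX
    b2 <- .ln_bwd(dN2, lc$ln2, p$ln2$g)
    grads$dec[[l]]$ln2$g <- b2$dg; grads$dec[[l]]$ln2$b <- b2$db
    dR2 <- b2$dX
    dA2 <- .apply_drop(dR2, lc$drop2)
    cb <- .mha_bwd(dA2, p$cross_attn, cfg, lc$cross, lc$ln1$Y, cache$memory,
                   tgt_in$off, tgt_in$len, src$off, src$len)
    grads$dec[[l]]$cross_attn <- cb$g
    dMem <- dMem + cb$dXkv
    dN1 <- dR2 + cb$dXq
    b1 <- .ln_bwd(dN1, lc$ln1, p$ln1$g)
    grads$dec[[l]]$ln1$g <- b1$dg; grads$dec[[l]]$ln1$b <- b1$db
    dR1 <- b1$dX
    dA1 <- .apply_drop(dR1, lc$drop1)
    sb <- .mha_bwd(dA1, p$self_attn, cfg, lc$self, lc$Y_in, lc$Y_in,
                   tgt_in$off, tgt_in$len, tgt_in$off, tgt_in$len)
    grads$dec[[l]]$self_attn <- sb$g
    dY <- dR1 + sb$dXq + sb$dXkv
  }
  dY <- .apply_drop(dY, cache$drop_tgt)
  # embedding gradient: accumulate rows (scaled by sqrt(d))
  grads$tgt_emb <- .accum_rows(grads$tgt_emb, tgt_in$ids, dY * sqrt(d))

  dX <- dMem
  for (l in rev(seq_along(params$enc))) {
    p <- params$enc[[l]]; lc <- cache$enc[[l]]
    b2 <- .ln_bwd(dX, lc$ln2, p$ln2$g)
    grads$enc[[l]]$ln2$g <- b2$dg; grads$enc[[l]]$ln2$b <- b2$db
    dR2 <- b2$dX
    dF <- .apply_drop(dR2, lc$drop2)
    fb <- .ff_bwd(dF, p$ff, lc$ff, lc$ln1$Y)
    grads$enc[[l]]$ff <- fb$g
    dN1 <- dR2 + fb$dX
    b1 <- .ln_bwd(dN1, lc$ln1, p$ln1$g)
    grads$enc[[l]]$ln1$g <- b1$dg; grads$enc[[l]]$ln1$b <- b1$db
    dR1 <- b1$dX
    dA <- .apply_drop(dR1, lc$drop1)
    ab <- .mha_bwd(dA, p$attn, cfg, lc$attn, lc$X_in, lc$X_in,
                   src$off, src$len, src$off, src$len)
    grads$enc[[l]]$attn <- ab$g
    dX <- dR1 + ab$dXq + ab$dXkv
  }
  dX <- .apply_drop(dX, cache$drop_src)
  grads$src_emb <- .accum_rows(grads$src_emb, src$ids, dX * sqrt(d))
  grads
}

.accum_rows <- function(G, ids, dX) {
  agg <- rowsum(dX, group = ids)
  rows <- as.integer(rownames(agg))
  G[rows, ] <- G[rows, , drop = FALSE] + agg
  G
}

# ---- optimizer --------------------------------------------------------

.adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1
  b1 <- opt$beta1; b2 <- opt$beta2
  opt$m <- .tree_map(function(m, g) b1 * m + (1 - b1) * g, opt$m, grads)
  opt$v <- .tree_map(function(v, g) b2 * v + (1 - b2) * g * g, opt$v, grads)
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  upd <- .tree_map(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + opt$eps),
                   opt$m, opt$v)
  params <- .tree_map(function(p, u) p - u, params, upd)
  list(opt = opt, params = params)
}

# Triangular cyclic learning rate over training steps.
.cyclic_lr <- function(step, base_lr, max_lr, cycle_steps, mode = "triangular") {
  if (cycle_steps <= 1) return(max_lr)
  pos <- ((step - 1) %% cycle_steps) / cycle_steps
  tri <- 1 - abs(2 * pos - 1)
  amp <- max_lr - base_lr
  if (mode == "triangular2") amp <- amp / 2^((step - 1) %/% cycle_steps)
  base_lr + amp * tri
}

# ---- autoregressive sampling ------------------------------------------

# Encoder forward in inference mode for a single id vector.
.encode_memory <- function(params, cfg, src_ids) {
  d <- cfg$d_model
  X <- params$src_emb[src_ids, , drop = FALSE] * sqrt(d) +
    positional_encoding(seq_along(src_ids) - 1, d)
  off <- 0L; len <- length(src_ids)
  for (l in seq_along(params$enc)) {
    p <- params$enc[[l]]
    a <- .mha_fwd(p$attn, cfg, X, X, off, len, off, len, causal = FALSE)
    n1 <- .ln_fwd(X + a$Out, p$ln1$g, p$ln1$b)
    f <- .ff_fwd(p$ff, n1$Y)
    X <- .ln_fwd(n1$Y + f$Y, p$ln2$g, p$ln2$b)$Y
  }
  X
}

# Batched multinomial/greedy decoding conditioned on one encoder memory.
# Returns an integer matrix (n x max_steps) of sampled token ids.
.decode_batch <- function(params, cfg, memory, n, temperature, max_steps,
                          start_id, end_id, greedy = FALSE) {
  d <- cfg$d_model; H <- cfg$n_heads; dh <- d %/% H
  nl <- length(params$dec)
  # cross-attention keys/values depend only on memory: precompute per layer
  crossKV <- lapply(params$dec, function(p)
    list(K = memory %*% p$cross_attn$Wk,
         V = memory %*% p$cross_attn$Wv))
  Kc <- lapply(seq_len(nl), function(l) array(0, c(n, max_steps, d)))
  Vc <- lapply(seq_len(nl), function(l) array(0, c(n, max_steps, d)))
  tokens <- matrix(0L, n, max_steps)
  cur <- rep(start_id, n)
  alive <- rep(TRUE, n)
  scale <- 1 / sqrt(dh)
  for (t in seq_len(max_steps)) {
    X <- params$tgt_emb[cur, , drop = FALSE] * sqrt(d) +
      matrix(positional_encoding(t - 1, d), n, d, byrow = TRUE)
    for (l in seq_len(nl)) {
      p <- params$dec[[l]]
      # self-attention with KV cache
      Q <- X %*% p$self_attn$Wq
      Kc[[l]][[t]] <- X %*% p$self_attn$Wk
      Vc[[l]][[t]] <- X %*% p$self_attn$Wv
      C <- matrix(0, n, d)
      for (h in seq_len(H)) {
        cols <- (h - 1) * dh + seq_len(dh)
        Qh <- Q[, cols, drop = FALSE]
        S <- matrix(0, n, t)
        for (j in seq_len(t)) {
          S[, j] <- rowSums(Qh * matrix(Kc[[l]][, j, cols], n, dh)) * scale
        }
        P <- .softmax_rows(S)
        Ch <- matrix(0, n, dh)
        for (j in seq_len(t)) {
          Ch <- Ch + P[, j] * matrix(Vc[[l]][, j, cols], n, dh)
        }
        C[, cols] <- Ch
      }
      A1 <- C %*% p$self_attn$Wo
      N1 <- .ln_fwd(X + A1, p$ln1$g, p$ln1$b)$Y
      # cross-attention against the shared memory
      Q <- N1 %*% p$cross_attn$Wq
      C <- matrix(0, n, d)
      for (h in seq_len(H)) {
        cols <- (h - 1) * dh + seq_len(dh)
        S <- (Q[, cols, drop = FALSE] %*% t(crossKV[[l]]$K[, cols, drop = FALSE])) * scale
        P <- .softmax_rows(S)
        C[, cols] <- P %*% crossKV[[l]]$V[, cols, drop = FALSE]
      }
      A2 <- C %*% p$cross_attn$Wo
      N2 <- .ln_fwd(N1 + A2, p$ln2$g, p$ln2$b)$Y
      f <- .ff_fwd(p$ff, N2)
      X <- .ln_fwd(N2 + f$Y, p$ln3$g, p$ln3$b)$Y
    }
    logits <- .linear_fwd(X, params$out$W, params$out$b)
    if (greedy) {
      nxt <- max.col(logits, ties.method = "first")
    } else {
      Pr <- .softmax_rows(logits / temperature)
      u <- stats::runif(n)
      cum <- Pr
      for (j in 2:ncol(Pr)) cum[, j] <- cum[, j - 1] + Pr[, j]
      nxt <- rowSums(u > cum) + 1L
    }
    nxt[!alive] <- end_id
    tokens[, t] <- nxt
    alive <- alive & nxt != end_id
    cur <- nxt
    if (!any(alive)) { tokens <- tokens[, seq_len(t), drop = FALSE]; break }
  }
  tokens
}
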