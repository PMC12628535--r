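# Layer primitives with explicit forward/backward passes.
#
# Batched sequence tensors are stored flat as (B*T) x C matrices with row
# r = b + (t-1)*B (column-major over batch then time), so reshaping a
# per-row vector with matrix(v, B, T) yields the (batch x time) layout.
# Every *_fwd returns list(out = ..., cache = ...); the matching *_bwd
# consumes the upstream gradient and the cache.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

dense_fwd <- function(X, W, b) {
  out <- X %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(X = X, W = W))
}

dense_bwd <- function(dY, cache) {
  list(dX = dY %*% t(cache$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

relu_fwd <- function(X) {
  keep <- X > 0
  list(out = X * keep, cache = keep)
}

relu_bwd <- function(dY, cache) dY * cache

# Inverted dropout: activations scaled by 1/(1-p) at train time so eval
# needs no rescaling.
dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, cache = NULL))
  keep <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(out = X * keep, cache = keep)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# Batch normalization per channel over all (batch x time) rows. `state`
# carries running mean/var (momentum 0.9) used in eval mode.
batchnorm_fwd <- function(X, gamma, beta, state, train,
                          momentum = 0.9, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc * xc)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- sweep(X, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                    train = train),
       state = state)
}

batchnorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, cache$gamma, "*")
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dX <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*")
    dX <- sweep(dX, 2, cache$inv_sd, "*")
  } else {
    dX <- sweep(dxhat, 2, cache$inv_sd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Group normalization: channels are split into `groups`; statistics are
# computed per sample over (time x channels-in-group).
groupnorm_fwd <- function(X, gamma, beta, B, T, groups = 4L, eps = 1e-5) {
  C <- ncol(X)
  stopifnot(C %% groups == 0)
  Cg <- C %/% groups
  bidx <- rep_len(seq_len(B), B * T)
  xhat <- X
  inv_sd_all <- matrix(0, B, groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1L) * Cg + 1L):(g * Cg)
    sub <- X[, cols, drop = FALSE]
    n <- T * Cg
    mu <- rowSums(rowsum(sub, bidx)) / n
    v <- rowSums(rowsum(sub * sub, bidx)) / n - mu^2
    inv_sd <- 1 / sqrt(v + eps)
    inv_sd_all[, g] <- inv_sd
    xhat[, cols] <- (sub - mu[bidx]) * inv_sd[bidx]
  }
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd_all, gamma = gamma,
                    B = B, T = T, groups = groups, Cg = Cg, bidx = bidx))
}

groupnorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, cache$gamma, "*")
  dX <- dxhat
  bidx <- cache$bidx
  for (g in seq_len(cache$groups)) {
    cols <- ((g - 1L) * cache$Cg + 1L):(g * cache$Cg)
    n <- cache$T * cache$Cg
    dxg <- dxhat[, cols, drop = FALSE]
    xg <- xhat[, cols, drop = FALSE]
    m1 <- rowSums(rowsum(dxg, bidx)) / n
    m2 <- rowSums(rowsum(dxg * xg, bidx)) / n
    inv_sd <- cache$inv_sd[, g]
    dX[, cols] <- (dxg - m1[bidx] - xg * m2[bidx]) * inv_sd[bidx]
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# 1-D convolution over the token axis, stride 1, same (zero) padding.
# Implemented by unfolding the input into (B*T) x (kernel*Din) and a
# single matrix product.
conv_unfold_idx <- function(B, T, kernel) {
  half <- (kernel - 1L) %/% 2L
  offsets <- seq.int(-half, half)
  r <- seq_len(B * T)
  t <- (r - 1L) %/% B + 1L
  idx <- lapply(offsets, function(o) {
    src <- r + o * B
    src[t + o < 1L | t + o > T] <- B * T + 1L  # points at the zero row
    src
  })
  list(offsets = offsets, idx = idx)
}

conv1d_fwd <- function(X, W, b, B, T, kernel = 3L) {
  Din <- ncol(X)
  ui <- conv_unfold_idx(B, T, kernel)
  Xpad <- rbind(X, 0)
  U <- do.call(cbind, lapply(ui$idx, function(ix) Xpad[ix, , drop = FALSE]))
  out <- sweep(U %*% W, 2, b, "+")
  list(out = out, cache = list(U = U, W = W, ui = ui, Din = Din,
                               B = B, T = T))
}

conv1d_bwd <- function(dY, cache) {
  dW <- crossprod(cache$U, dY)
  db <- colSums(dY)
  dU <- dY %*% t(cache$W)
  B <- cache$B; T <- cache$T; Din <- cache$Din
  dX <- matrix(0, B * T, Din)
  for (j in seq_along(cache$ui$idx)) {
    cols <- ((j - 1L) * Din + 1L):(j * Din)
    ix <- cache$ui$idx[[j]]
    valid <- ix <= B * T
    blk <- dU[valid, cols, drop = FALSE]
    tgt <- ix[valid]
    dX[tgt, ] <- dX[tgt, ] + blk
  }
  list(dX = dX, dW = dW, db = db)
}

lstm_init <- function(din, hidden) {
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  list(W = glorot(din, 4L * hidden), U = glorot(hidden, 4L * hidden), b = b)
}

# Single-direction LSTM over T steps (gate order i, f, g, o). `reverse`
# runs the recurrence from t = T down to 1; outputs stay at their original
# time positions.
lstm_fwd <- function(X, p, B, T, reverse = FALSE) {
  H <- length(p$b) %/% 4L
  order_t <- if (reverse) rev(seq_len(T)) else seq_len(T)
  Hout <- matrix(0, B * T, H)
  h <- matrix(0, B, H)
  cst <- matrix(0, B, H)
  steps <- vector("list", T)
  for (s in seq_len(T)) {
    t <- order_t[s]
    rows <- ((t - 1L) * B + 1L):(t * B)
    Xt <- X[rows, , drop = FALSE]
    G <- Xt %*% p$W + h %*% p$U
    G <- sweep(G, 2, p$b, "+")
    i <- sigmoid(G[, 1:H, drop = FALSE])
    f <- sigmoid(G[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(G[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(G[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    Hout[rows, ] <- h
    steps[[s]] <- list(rows = rows, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = Hout, h_last = h,
       cache = list(steps = steps, p = p, X = X, B = B, T = T, H = H))
}

lstm_bwd <- function(dH, dh_last, cache) {
  p <- cache$p
  H <- cache$H
  B <- cache$B
  T <- cache$T
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  dU <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  dh_carry <- if (is.null(dh_last)) matrix(0, B, H) else dh_last
  dc_carry <- matrix(0, B, H)
  for (s in rev(seq_len(T))) {
    st <- cache$steps[[s]]
    dh <- dH[st$rows, , drop = FALSE] + dh_carry
    do <- dh * st$tc
    dc <- dc_carry + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_carry <- dc * st$f
    dG <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    Xt <- cache$X[st$rows, , drop = FALSE]
    dW <- dW + crossprod(Xt, dG)
    dU <- dU + crossprod(st$h_prev, dG)
    db <- db + colSums(dG)
    dX[st$rows, ] <- dX[st$rows, ] + dG %*% t(p$W)
    dh_carry <- dG %*% t(p$U)
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Additive attention pooling: e_t = v' tanh(Wa' h_t + ba); a = softmax(e);
# c = sum_t a_t h_t.
attn_fwd <- function(Hseq, Wa, ba, v, B, T) {
  u <- tanh(sweep(Hseq %*% Wa, 2, ba, "+"))
  e <- matrix(as.vector(u %*% v), B, T)
  a <- softmax_rows(e)
  aw <- as.vector(a)
  bidx <- rep_len(seq_len(B), B * T)
  ctx <- rowsum(Hseq * aw, bidx)
  list(out = ctx, weights = a,
       cache = list(Hseq = Hseq, u = u, a = a, aw = aw, bidx = bidx,
                    Wa = Wa, v = v, B = B, T = T))
}

attn_bwd <- function(dctx, cache) {
  Hseq <- cache$Hseq
  bidx <- cache$bidx
  dH <- cache$aw * dctx[bidx, , drop = FALSE]
  da_vec <- rowSums(dctx[bidx, , drop = FALSE] * Hseq)
  da <- matrix(da_vec, cache$B, cache$T)
  a <- cache$a
  de <- a * (da - rowSums(a * da))
  de_vec <- as.vector(de)
  dv <- as.vector(crossprod(cache$u, de_vec))
  du <- outer(de_vec, cache$v)
  dpre <- du * (1 - cache$u^2)
  dWa <- crossprod(Hseq, dpre)
  dba <- colSums(dpre)
  dH <- dH + dpre %*% t(cache$Wa)
  list(dH = dH, dWa = dWa, dba = dba, dv = dv)
}
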