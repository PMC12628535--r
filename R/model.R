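# Dual-branch encoder: branch 1 = CNN -> ReLU -> BatchNorm -> dropout ->
# BiLSTM -> GroupNorm -> dropout -> attention pooling over the k-mer
# embedding view; branch 2 = BiLSTM final-state summary over the CGR state
# view. The fused representation h = [context ; summary] feeds both the
# projection head (contrastive objective, training only) and the
# classification head (inference path).

#' Model architecture configuration
#'
#' All layer sizes follow the reference architecture: 64 LSTM hidden units
#' per direction in both branches (so 128-dimensional branch outputs),
#' classifier stack 256 -> 128 -> 64 -> 2, dropout 0.3 after the
#' convolutional and BiLSTM blocks of branch 1 and 0.1 in the dense heads,
#' batch normalization after the convolution and 4-group group
#' normalization after the branch-1 BiLSTM. Choices the reference leaves
#' open default to: 64 convolution filters of width 3, projection output
#' dimension P = 64 with one 128-unit hidden layer, temperature
#' `tau = 0.5`.
#'
#' @param k k-mer size of the primary view tokenizer (default 6).
#' @param embed_dim lookup embedding dimension (default 32; 768 for
#'   transformer-scale parity).
#' @param L0 standardized window length (default 41).
#' @param conv_filters,kernel 1-D convolution filter count and width.
#' @param lstm_hidden hidden units per LSTM direction (both branches).
#' @param attn_dim width of the attention scoring layer.
#' @param proj_hidden,proj_dim projection-head hidden width and output
#'   dimension P.
#' @param clf_dims classifier hidden layer widths.
#' @param dropout_conv,dropout_lstm,dropout_head dropout rates.
#' @param gn_groups group-normalization group count.
#' @param use_branch1,use_branch2 ablation switches; disabling a branch
#'   removes its contribution from h.
#' @param branch1_arch branch-1 depth for ablations: `"cba"` (full
#'   CNN-BiLSTM-attention, default), `"cnn_bilstm"` (mean pooling instead
#'   of attention) or `"cnn"` (convolution block with mean pooling, no
#'   recurrence).
#' @param use_contrastive whether training adds the contrastive term.
#' @param branch2_summary `"final"` concatenates the two directions' final
#'   hidden states; `"mean"` mean-pools the per-position outputs.
#' @param tau contrastive temperature.
#' @param seed parameter-initialization seed.
#' @return a `model_config` list.
#' @export
model_config <- function(k = 6L, embed_dim = 32L, L0 = 41L,
                         conv_filters = 64L, kernel = 3L,
                         lstm_hidden = 64L, attn_dim = 64L,
                         proj_hidden = 128L, proj_dim = 64L,
                         clf_dims = c(256L, 128L, 64L),
                         dropout_conv = 0.3, dropout_lstm = 0.3,
                         dropout_head = 0.1, gn_groups = 4L,
                         use_branch1 = TRUE, use_branch2 = TRUE,
                         branch1_arch = c("cba", "cnn_bilstm", "cnn"),
                         use_contrastive = TRUE,
                         branch2_summary = c("final", "mean"),
                         tau = 0.5, seed = 1L) {
  cfg <- list(k = as.integer(k), embed_dim = as.integer(embed_dim),
              L0 = as.integer(L0), conv_filters = as.integer(conv_filters),
              kernel = as.integer(kernel), lstm_hidden = as.integer(lstm_hidden),
              attn_dim = as.integer(attn_dim),
              proj_hidden = as.integer(proj_hidden),
              proj_dim = as.integer(proj_dim), clf_dims = as.integer(clf_dims),
              dropout_conv = dropout_conv, dropout_lstm = dropout_lstm,
              dropout_head = dropout_head, gn_groups = as.integer(gn_groups),
              use_branch1 = isTRUE(use_branch1),
              use_branch2 = isTRUE(use_branch2),
              branch1_arch = match.arg(branch1_arch),
              use_contrastive = isTRUE(use_contrastive),
              branch2_summary = match.arg(branch2_summary),
              tau = tau, seed = as.integer(seed))
  if (!cfg$use_branch1 && !cfg$use_branch2) {
    stop("at least one encoder branch must be enabled")
  }
  b1_dim <- if (!cfg$use_branch1) 0L else if (cfg$branch1_arch == "cnn") {
    cfg$conv_filters
  } else 2L * cfg$lstm_hidden
  cfg$b1_dim <- b1_dim
  cfg$h_dim <- b1_dim + 2L * cfg$lstm_hidden * cfg$use_branch2
  if (cfg$proj_dim >= cfg$h_dim) {
    warning(sprintf(
      "projection dimension P = %d is not smaller than dim(h) = %d; the head is meant to compress",
      cfg$proj_dim, cfg$h_dim))
  }
  structure(cfg, class = "model_config")
}

#' Initialize a dual-branch multi-view model
#'
#' @param config a [model_config()].
#' @param backend an `embedding_backend`; defaults to a seeded
#'   [lookup_backend()] matching the config.
#' @return an `mv_model`: list with `params` (named list of weight
#'   matrices/vectors), `config`, `backend` and batch-norm running state.
#' @export
mv_model <- function(config = model_config(), backend = NULL) {
  if (is.null(backend)) {
    backend <- lookup_backend(k = config$k, d = config$embed_dim,
                              seed = config$seed)
  }
  stopifnot(inherits(backend, "embedding_backend"))
  old <- .Random.seed_get()
  set.seed(config$seed + 1L)
  H <- config$lstm_hidden
  Fc <- config$conv_filters
  D <- ncol(backend$E)
  p <- list()
  if (config$use_branch1) {
    p$c_W <- glorot(config$kernel * D, Fc)
    p$c_b <- numeric(Fc)
    p$bn_gamma <- rep(1, Fc)
    p$bn_beta <- numeric(Fc)
    if (config$branch1_arch != "cnn") {
      l1f <- lstm_init(Fc, H); l1b <- lstm_init(Fc, H)
      p$l1f_W <- l1f$W; p$l1f_U <- l1f$U; p$l1f_b <- l1f$b
      p$l1b_W <- l1b$W; p$l1b_U <- l1b$U; p$l1b_b <- l1b$b
      p$gn_gamma <- rep(1, 2L * H)
      p$gn_beta <- numeric(2L * H)
    }
    if (config$branch1_arch == "cba") {
      p$a_Wa <- glorot(2L * H, config$attn_dim)
      p$a_ba <- numeric(config$attn_dim)
      p$a_v <- stats::runif(config$attn_dim, -0.1, 0.1)
    }
  }
  if (config$use_branch2) {
    l2f <- lstm_init(1L, H); l2b <- lstm_init(1L, H)
    p$l2f_W <- l2f$W; p$l2f_U <- l2f$U; p$l2f_b <- l2f$b
    p$l2b_W <- l2b$W; p$l2b_U <- l2b$U; p$l2b_b <- l2b$b
  }
  hd <- config$h_dim
  p$p_W1 <- glorot(hd, config$proj_hidden)
  p$p_b1 <- numeric(config$proj_hidden)
  p$p_W2 <- glorot(config$proj_hidden, config$proj_dim)
  # small nonzero bias: keeps initial projections off the exact origin,
  # where the cosine similarity is undefined
  p$p_b2 <- stats::runif(config$proj_dim, -0.01, 0.01)
  dims <- c(hd, config$clf_dims, 2L)
  for (i in seq_len(length(dims) - 1L)) {
    p[[sprintf("f_W%d", i)]] <- glorot(dims[i], dims[i + 1L])
    p[[sprintf("f_b%d", i)]] <- numeric(dims[i + 1L])
  }
  .Random.seed_restore(old)
  structure(list(params = p, config = config, backend = backend,
                 bn_state = list(mean = numeric(Fc), var = rep(1, Fc))),
            class = "mv_model")
}

#' @export
print.mv_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L)) +
    if (x$backend$trainable) length(x$backend$E) else 0L
  cat(sprintf(
    "<mv_model> k=%d embed_dim=%d h_dim=%d (%s%s) %s backend, %d trainable parameters\n",
    x$config$k, ncol(x$backend$E), x$config$h_dim,
    if (x$config$use_branch1) "branch1 " else "",
    if (x$config$use_branch2) "branch2" else "",
    x$backend$type, np))
  invisible(x)
}

# ---- batched encoder forward/backward (internal) -------------------------

# X_flat: (B*T) x D embedded tokens (row r = b + (t-1)*B); Xe: B x L0 CGR
# states. Either may be NULL when the corresponding branch is disabled.
encoder_fwd_batch <- function(model, X_flat, Xe, B, train = FALSE) {
  cfg <- model$config
  p <- model$params
  cache <- list(B = B)
  parts <- list()
  if (cfg$use_branch1) {
    T1 <- nrow(X_flat) %/% B
    cv <- conv1d_fwd(X_flat, p$c_W, p$c_b, B, T1, cfg$kernel)
    rl <- relu_fwd(cv$out)
    bn <- batchnorm_fwd(rl$out, p$bn_gamma, p$bn_beta, model$bn_state, train)
    model$bn_state <- bn$state
    dp1 <- dropout_fwd(bn$out, cfg$dropout_conv, train)
    cache$b1 <- list(T1 = T1, cv = cv$cache, rl = rl$cache, bn = bn$cache,
                     dp1 = dp1$cache)
    bidx <- rep_len(seq_len(B), B * T1)
    if (cfg$branch1_arch == "cnn") {
      parts$context <- rowsum(dp1$out, bidx) / T1
      cache$branch1_seq <- dp1$out
    } else {
      lf <- lstm_fwd(dp1$out, list(W = p$l1f_W, U = p$l1f_U, b = p$l1f_b),
                     B, T1, reverse = FALSE)
      lb <- lstm_fwd(dp1$out, list(W = p$l1b_W, U = p$l1b_U, b = p$l1b_b),
                     B, T1, reverse = TRUE)
      Hseq <- cbind(lf$out, lb$out)
      gn <- groupnorm_fwd(Hseq, p$gn_gamma, p$gn_beta, B, T1, cfg$gn_groups)
      dp2 <- dropout_fwd(gn$out, cfg$dropout_lstm, train)
      cache$b1 <- c(cache$b1, list(lf = lf$cache, lb = lb$cache,
                                   gn = gn$cache, dp2 = dp2$cache))
      if (cfg$branch1_arch == "cba") {
        at <- attn_fwd(dp2$out, p$a_Wa, p$a_ba, p$a_v, B, T1)
        parts$context <- at$out
        cache$b1$at <- at$cache
        cache$attn_weights <- at$weights
      } else {
        parts$context <- rowsum(dp2$out, bidx) / T1
      }
      cache$branch1_seq <- dp2$out
    }
  }
  if (cfg$use_branch2) {
    L <- ncol(Xe)
    Xe_flat <- matrix(as.vector(Xe), B * L, 1L)
    lf2 <- lstm_fwd(Xe_flat, list(W = p$l2f_W, U = p$l2f_U, b = p$l2f_b),
                    B, L, reverse = FALSE)
    lb2 <- lstm_fwd(Xe_flat, list(W = p$l2b_W, U = p$l2b_U, b = p$l2b_b),
                    B, L, reverse = TRUE)
    if (cfg$branch2_summary == "final") {
      parts$summary <- cbind(lf2$h_last, lb2$h_last)
    } else {
      bidx <- rep_len(seq_len(B), B * L)
      parts$summary <- cbind(rowsum(lf2$out, bidx), rowsum(lb2$out, bidx)) / L
    }
    cache$b2 <- list(L = L, lf2 = lf2$cache, lb2 = lb2$cache)
  }
  h <- do.call(cbind, parts)
  cache$parts <- names(parts)
  list(h = h, cache = cache, model = model)
}

encoder_bwd_batch <- function(model, dh, cache) {
  cfg <- model$config
  H2 <- 2L * cfg$lstm_hidden
  g <- list()
  dX <- NULL
  col0 <- 0L
  if (cfg$use_branch1) {
    dctx <- dh[, (col0 + 1L):(col0 + cfg$b1_dim), drop = FALSE]
    col0 <- col0 + cfg$b1_dim
    b1 <- cache$b1
    B <- cache$B
    T1 <- b1$T1
    bidx <- rep_len(seq_len(B), B * T1)
    if (cfg$branch1_arch == "cnn") {
      dconv_in <- dropout_bwd(dctx[bidx, , drop = FALSE] / T1, b1$dp1)
    } else {
      dseq <- if (cfg$branch1_arch == "cba") {
        at <- attn_bwd(dctx, b1$at)
        g$a_Wa <- at$dWa; g$a_ba <- at$dba; g$a_v <- at$dv
        at$dH
      } else {
        dctx[bidx, , drop = FALSE] / T1
      }
      dseq <- dropout_bwd(dseq, b1$dp2)
      gn <- groupnorm_bwd(dseq, b1$gn)
      g$gn_gamma <- gn$dgamma; g$gn_beta <- gn$dbeta
      H1 <- cfg$lstm_hidden
      lf <- lstm_bwd(gn$dX[, 1:H1, drop = FALSE], NULL, b1$lf)
      lb <- lstm_bwd(gn$dX[, (H1 + 1L):(2L * H1), drop = FALSE], NULL, b1$lb)
      g$l1f_W <- lf$dW; g$l1f_U <- lf$dU; g$l1f_b <- lf$db
      g$l1b_W <- lb$dW; g$l1b_U <- lb$dU; g$l1b_b <- lb$db
      dconv_in <- dropout_bwd(lf$dX + lb$dX, b1$dp1)
    }
    bn <- batchnorm_bwd(dconv_in, b1$bn)
    g$bn_gamma <- bn$dgamma; g$bn_beta <- bn$dbeta
    drl <- relu_bwd(bn$dX, b1$rl)
    cv <- conv1d_bwd(drl, b1$cv)
    g$c_W <- cv$dW; g$c_b <- cv$db
    dX <- cv$dX
  }
  if (cfg$use_branch2) {
    dsum <- dh[, (col0 + 1L):(col0 + H2), drop = FALSE]
    b2 <- cache$b2
    H1 <- cfg$lstm_hidden
    B <- cache$B
    L <- b2$L
    zero <- matrix(0, B * L, H1)
    if (cfg$branch2_summary == "final") {
      lf2 <- lstm_bwd(zero, dsum[, 1:H1, drop = FALSE], b2$lf2)
      lb2 <- lstm_bwd(zero, dsum[, (H1 + 1L):(2L * H1), drop = FALSE], b2$lb2)
    } else {
      bidx <- rep_len(seq_len(B), B * L)
      df <- dsum[, 1:H1, drop = FALSE][bidx, , drop = FALSE] / L
      dbk <- dsum[, (H1 + 1L):(2L * H1), drop = FALSE][bidx, , drop = FALSE] / L
      lf2 <- lstm_bwd(df, NULL, b2$lf2)
      lb2 <- lstm_bwd(dbk, NULL, b2$lb2)
    }
    g$l2f_W <- lf2$dW; g$l2f_U <- lf2$dU; g$l2f_b <- lf2$db
    g$l2b_W <- lb2$dW; g$l2b_U <- lb2$dU; g$l2b_b <- lb2$db
    dXe <- matrix(lf2$dX + lb2$dX, B, L)
  } else {
    dXe <- NULL
  }
  list(grads = g, dX = dX, dXe = dXe)
}

# ---- heads ---------------------------------------------------------------

projection_fwd <- function(model, h, train = FALSE) {
  p <- model$params
  d1 <- dense_fwd(h, p$p_W1, p$p_b1)
  r1 <- relu_fwd(d1$out)
  dp <- dropout_fwd(r1$out, model$config$dropout_head, train)
  d2 <- dense_fwd(dp$out, p$p_W2, p$p_b2)
  list(z = d2$out, cache = list(d1 = d1$cache, r1 = r1$cache,
                                dp = dp$cache, d2 = d2$cache))
}

projection_bwd <- function(model, dz, cache) {
  g <- list()
  d2 <- dense_bwd(dz, cache$d2)
  g$p_W2 <- d2$dW; g$p_b2 <- d2$db
  dd <- dropout_bwd(d2$dX, cache$dp)
  dr <- relu_bwd(dd, cache$r1)
  d1 <- dense_bwd(dr, cache$d1)
  g$p_W1 <- d1$dW; g$p_b1 <- d1$db
  list(grads = g, dh = d1$dX)
}

classifier_fwd <- function(model, h, train = FALSE) {
  p <- model$params
  nlayer <- length(model$config$clf_dims) + 1L
  x <- h
  caches <- vector("list", nlayer)
  for (i in seq_len(nlayer)) {
    d <- dense_fwd(x, p[[sprintf("f_W%d", i)]], p[[sprintf("f_b%d", i)]])
    if (i < nlayer) {
      r <- relu_fwd(d$out)
      dp <- dropout_fwd(r$out, model$config$dropout_head, train)
      x <- dp$out
      caches[[i]] <- list(d = d$cache, r = r$cache, dp = dp$cache)
    } else {
      x <- d$out
      caches[[i]] <- list(d = d$cache)
    }
  }
  probs <- softmax_rows(x)
  list(probs = probs, logits = x, cache = caches)
}

# dlogits: upstream gradient on the pre-softmax logits (for cross-entropy
# training use (probs - Y) / N directly).
classifier_bwd <- function(model, dlogits, cache) {
  nlayer <- length(cache)
  g <- list()
  dx <- dlogits
  for (i in rev(seq_len(nlayer))) {
    d <- dense_bwd(dx, cache[[i]]$d)
    g[[sprintf("f_W%d", i)]] <- d$dW
    g[[sprintf("f_b%d", i)]] <- d$db
    dx <- d$dX
    if (i > 1L) {
      dx <- dropout_bwd(dx, cache[[i - 1L]]$dp)
      dx <- relu_bwd(dx, cache[[i - 1L]]$r)
    }
  }
  list(grads = g, dh = dx)
}

# ---- exported single-sample operations -----------------------------------

#' Branch-1 forward pass (CNN -> BiLSTM -> attention) for one sample
#'
#' @param model an [mv_model()] with branch 1 enabled.
#' @param X embedded token matrix (tokens x d) or an `embedded_sequence`.
#' @param train logical; enables dropout and batch-statistics
#'   normalization (training mode). Default `FALSE` (deterministic).
#' @return list with `seq` (per-timestep BiLSTM features, tokens x 2H),
#'   `context` (attention-pooled vector, length 2H) and `weights`
#'   (attention weights over timesteps).
#' @export
branch1_forward <- function(model, X, train = FALSE) {
  stopifnot(inherits(model, "mv_model"))
  if (!model$config$use_branch1) stop("branch 1 is disabled in this model")
  if (inherits(X, "embedded_sequence")) X <- X$X
  if (!is.matrix(X)) stop("X must be a (tokens x d) matrix")
  old <- model$config$use_branch2
  model$config$use_branch2 <- FALSE
  enc <- encoder_fwd_batch(model, X, NULL, B = 1L, train = train)
  model$config$use_branch2 <- old
  list(seq = enc$cache$branch1_seq,
       context = as.vector(enc$h),
       weights = as.vector(enc$cache$attn_weights))
}

#' Branch-2 forward pass (BiLSTM over CGR states) for one sample
#'
#' @param model an [mv_model()] with branch 2 enabled.
#' @param X_extra CGR state matrix (L0 x 1) or numeric vector.
#' @param train logical training mode.
#' @return numeric summary vector (length 2H).
#' @export
branch2_forward <- function(model, X_extra, train = FALSE) {
  stopifnot(inherits(model, "mv_model"))
  if (!model$config$use_branch2) stop("branch 2 is disabled in this model")
  Xe <- matrix(as.numeric(as.matrix(X_extra)), nrow = 1L)
  old <- model$config$use_branch1
  model$config$use_branch1 <- FALSE
  enc <- encoder_fwd_batch(model, NULL, Xe, B = 1L, train = train)
  model$config$use_branch1 <- old
  as.vector(enc$h)
}

#' Attention pooling over per-timestep features
#'
#' Scores each timestep with `e_t = v' tanh(W_a' h_t + b_a)`, normalizes
#' to weights `a = softmax(e)` and returns the weighted context
#' `c = sum_t a_t h_t`.
#'
#' @param H per-timestep feature matrix (T x C), T >= 1.
#' @param W_a affine map (C x A).
#' @param b_a bias (length A).
#' @param v scoring vector (length A).
#' @return list with `weights` (length T, non-negative, sums to 1) and
#'   `context` (length C).
#' @export
attention_pool <- function(H, W_a, b_a, v) {
  if (!is.matrix(H) || nrow(H) == 0) {
    stop("H must be a non-empty (timesteps x features) matrix")
  }
  at <- attn_fwd(H, W_a, b_a, v, B = 1L, T = nrow(H))
  list(weights = as.vector(at$weights), context = as.vector(at$out))
}

#' Encode one multi-view sample into the fused representation h
#'
#' @param model an [mv_model()].
#' @param sample list with `X` (embedded token matrix, used when branch 1
#'   is enabled) and `X_extra` (CGR state vector/matrix, used when branch 2
#'   is enabled).
#' @param train logical training mode.
#' @return an `encoder_output`: list with `h` (fused vector), `context`,
#'   `attn_weights`, `branch1_seq` and `branch2_summary` (NULL for
#'   disabled branches).
#' @export
encode <- function(model, sample, train = FALSE) {
  stopifnot(inherits(model, "mv_model"))
  cfg <- model$config
  X <- if (cfg$use_branch1) {
    if (inherits(sample$X, "embedded_sequence")) sample$X$X else sample$X
  } else NULL
  Xe <- if (cfg$use_branch2) {
    matrix(as.numeric(as.matrix(sample$X_extra)), nrow = 1L)
  } else NULL
  if (cfg$use_branch1 && is.null(X)) stop("sample lacks the X view")
  if (cfg$use_branch2 && is.null(sample$X_extra)) {
    stop("sample lacks the X_extra view")
  }
  enc <- encoder_fwd_batch(model, X, Xe, B = 1L, train = train)
  H2 <- 2L * cfg$lstm_hidden
  structure(list(
    h = as.vector(enc$h),
    context = if (cfg$use_branch1) as.vector(enc$h)[1:cfg$b1_dim] else NULL,
    attn_weights = if (cfg$use_branch1 && cfg$branch1_arch == "cba") {
      as.vector(enc$cache$attn_weights)
    } else NULL,
    branch1_seq = enc$cache$branch1_seq,
    branch2_summary = if (cfg$use_branch2) {
      as.vector(enc$h)[(cfg$h_dim - H2 + 1L):cfg$h_dim]
    } else NULL
  ), class = "encoder_output")
}

#' Project a fused representation into the contrastive space
#'
#' One-hidden-layer MLP mapping h to the `P`-dimensional vector z on which
#' the contrastive loss is computed. The head is used during training only
#' and discarded at inference.
#'
#' @param model an [mv_model()].
#' @param h fused representation (vector or one-row matrix).
#' @param train logical training mode (dropout in the dense layers).
#' @return numeric vector z of length `proj_dim`.
#' @export
project <- function(model, h, train = FALSE) {
  h <- matrix(as.numeric(h), nrow = 1L)
  as.vector(projection_fwd(model, h, train)$z)
}

#' Classify a fused representation
#'
#' Dense stack 256 -> 128 -> 64 -> 2 (ReLU, dropout 0.1) with a softmax
#' output over (unmodified, modified).
#'
#' @param model an [mv_model()].
#' @param h fused representation (vector or one-row matrix).
#' @param train logical training mode.
#' @return numeric probability vector of length 2 summing to 1; element 2
#'   is the modified-site probability.
#' @export
classify <- function(model, h, train = FALSE) {
  h <- matrix(as.numeric(h), nrow = 1L)
  as.vector(classifier_fwd(model, h, train)$probs)
}
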