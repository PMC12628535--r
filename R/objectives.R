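#' Cosine similarity between two vectors
#'
#' `u'v / (||u|| ||v||)`, in \[-1, 1\]. Zero vectors are an error (the
#' similarity is undefined).
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return scalar cosine similarity.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Assemble a contrastive batch
#'
#' Rows of `Z` are the 2N projected views, interleaved so that rows
#' `(2k-1, 2k)` are the positive pair derived from sample k.
#'
#' @param Z numeric matrix (2N x P) of projections.
#' @param tau temperature, > 0.
#' @return a `contrastive_batch` list with `Z`, `tau`, `N`.
#' @export
contrastive_batch <- function(Z, tau = 0.5) {
  if (!is.matrix(Z) || nrow(Z) %% 2L != 0L) {
    stop("Z must be a matrix with an even number of rows (2N views)")
  }
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  structure(list(Z = Z, tau = tau, N = nrow(Z) %/% 2L),
            class = "contrastive_batch")
}

# Row-normalized similarity matrix S_ij = cos(z_i, z_j).
.ntxent_sim <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm == 0)) stop("contrastive batch contains a zero projection")
  Zn <- Z / nrm
  tcrossprod(Zn)
}

#' Directed NT-Xent loss of one positive pair
#'
#' `-log exp(sim(q,k)/tau) / sum_{j != q} exp(sim(q,j)/tau)`, the
#' normalized temperature-scaled cross-entropy for anchor `q` with
#' positive `k`; all other 2(N-1) views in the batch act as negatives.
#'
#' @param batch a [contrastive_batch()].
#' @param q,k row indices of the anchor and its positive view.
#' @return non-negative scalar loss.
#' @export
ntxent_pair_loss <- function(batch, q, k) {
  stopifnot(inherits(batch, "contrastive_batch"))
  n2 <- 2L * batch$N
  if (q < 1 || q > n2 || k < 1 || k > n2 || q == k) {
    stop("invalid pair indices for this batch")
  }
  S <- .ntxent_sim(batch$Z) / batch$tau
  denom <- sum(exp(S[q, -q]))
  -(S[q, k] - log(denom))
}

#' Batch NT-Xent contrastive loss
#'
#' Mean of both directed pair losses over all N positive pairs:
#' `(1/2N) sum_k [loss(2k-1, 2k) + loss(2k, 2k-1)]`.
#'
#' @param batch a [contrastive_batch()].
#' @return scalar loss.
#' @export
ntxent_batch_loss <- function(batch) {
  stopifnot(inherits(batch, "contrastive_batch"))
  S <- .ntxent_sim(batch$Z) / batch$tau
  n2 <- 2L * batch$N
  total <- 0
  for (kk in seq_len(batch$N)) {
    a <- 2L * kk - 1L; b <- 2L * kk
    total <- total - (S[a, b] - log(sum(exp(S[a, -a]))))
    total <- total - (S[b, a] - log(sum(exp(S[b, -b]))))
  }
  total / n2
}

# Loss and gradient wrt Z for the batched NT-Xent (views interleaved).
# Row norms are clamped below at 1e-8 so an (initialization-transient)
# zero projection yields a finite gradient instead of aborting training.
ntxent_loss_grad <- function(Z, tau) {
  n2 <- nrow(Z)
  nrm <- pmax(sqrt(rowSums(Z^2)), 1e-8)
  Zn <- Z / nrm
  S <- tcrossprod(Zn) / tau
  # partner[q]: views interleaved, 2k-1 <-> 2k
  partner <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
  Sexp <- exp(S)
  diag(Sexp) <- 0
  denom <- rowSums(Sexp)
  loss <- mean(-(S[cbind(seq_len(n2), partner)] - log(denom)))
  # dL/dS[q,j] = (1/2N) * (softmax_j - 1[j = partner(q)]) / tau for j != q
  P <- Sexp / denom
  dS <- P
  dS[cbind(seq_len(n2), partner)] <- dS[cbind(seq_len(n2), partner)] - 1
  dS <- dS / (n2 * tau)
  diag(dS) <- 0
  # S = Zn Zn'; dZn = (dS + dS') Zn
  dZn <- (dS + t(dS)) %*% Zn
  # row normalization backward: dZ = (dZn - Zn * rowSums(dZn * Zn)) / nrm
  dZ <- (dZn - Zn * rowSums(dZn * Zn)) / nrm
  list(loss = loss, dZ = dZ)
}

#' Categorical cross-entropy loss
#'
#' `-(1/N) sum_i sum_c y_ic log(p_ic)`; predicted probabilities are
#' clamped below at `eps` so a zero on the true class yields a large but
#' finite loss.
#'
#' @param probs numeric matrix (N x 2) of predicted class probabilities
#'   (or a length-2 vector for one sample).
#' @param labels binary vector (1 = modified) or N x 2 one-hot matrix.
#' @param eps clamp floor (default 1e-12).
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels, eps = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (is.null(dim(labels))) {
    Y <- cbind(1 - labels, labels)
  } else Y <- labels
  stopifnot(nrow(Y) == nrow(probs))
  -mean(rowSums(Y * log(pmax(probs, eps))))
}

#' Combined multi-task objective
#'
#' `L_total = L_cls + lambda * L_cont` with `lambda` constrained to
#' \[0.3, 0.5\].
#'
#' @param cls_loss classification loss.
#' @param cont_loss contrastive loss.
#' @param lambda weighting in \[0.3, 0.5\].
#' @return scalar total loss.
#' @export
total_loss <- function(cls_loss, cont_loss, lambda) {
  if (!is.numeric(lambda) || lambda < 0.3 - 1e-12 || lambda > 0.5 + 1e-12) {
    stop("lambda must lie in [0.3, 0.5]")
  }
  cls_loss + lambda * cont_loss
}

#' Create the adaptive multi-task training state
#'
#' @param lambda initial contrastive weight (default 0.5).
#' @param window sliding-window length for the validation trend (default 5
#'   epochs).
#' @param step per-trigger adjustment of lambda (default 0.05).
#' @param warmup_epochs epochs during which lambda stays fixed (default
#'   10).
#' @return a `training_state` list.
#' @export
training_state <- function(lambda = 0.5, window = 5L, step = 0.05,
                           warmup_epochs = 10L) {
  structure(list(lambda = lambda, epoch = 0L, val_acc_history = numeric(0),
                 window = as.integer(window), step = step,
                 warmup_epochs = as.integer(warmup_epochs),
                 lambda_min = 0.3, lambda_max = 0.5),
            class = "training_state")
}

#' Update the adaptive contrastive weight lambda
#'
#' lambda stays fixed at 0.5 for the first 10 epochs. Afterwards the trend
#' of validation accuracy over a 5-epoch sliding window (sign of the
#' least-squares slope) drives lambda down by `step` (floor 0.3) on a
#' negative trend and up by `step` (ceiling 0.5) on a positive trend.
#'
#' @param state a [training_state()] whose `epoch` (1-based, just
#'   completed) and `val_acc_history` are current.
#' @return the updated `training_state`.
#' @export
update_lambda <- function(state) {
  stopifnot(inherits(state, "training_state"))
  if (state$epoch < state$warmup_epochs) return(state)
  n <- length(state$val_acc_history)
  if (n < state$window) return(state)
  acc <- utils::tail(state$val_acc_history, state$window)
  x <- seq_along(acc)
  slope <- sum((x - mean(x)) * (acc - mean(acc))) / sum((x - mean(x))^2)
  if (slope < 0) {
    state$lambda <- max(state$lambda - state$step, state$lambda_min)
  } else if (slope > 0) {
    state$lambda <- min(state$lambda + state$step, state$lambda_max)
  }
  state
}

#' Learning-rate schedule: 5-epoch linear warm-up, then 0.9 exponential decay
#'
#' Epochs are 0-based: epochs 0..4 ramp linearly from `base_lr / 5` to
#' `base_lr`; epoch `e >= 5` yields `base_lr * 0.9^(e - 4)`.
#'
#' @param epoch 0-based epoch index.
#' @param base_lr peak learning rate.
#' @param warmup warm-up length in epochs (default 5).
#' @param decay per-epoch decay rate after warm-up (default 0.9).
#' @return learning rate for the epoch.
#' @export
lr_schedule <- function(epoch, base_lr = 1e-3, warmup = 5L, decay = 0.9) {
  stopifnot(epoch >= 0)
  if (epoch < warmup) {
    base_lr * (epoch + 1) / warmup
  } else {
    base_lr * decay^(epoch - warmup + 1)
  }
}
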