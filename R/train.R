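#' Training hyperparameter configuration
#'
#' Defaults: Adam with base learning rate 1e-3 on a 5-epoch warm-up /
#' 0.9-decay schedule, batch size 32, early stopping on validation
#' accuracy with patience 15, contrastive weight lambda starting at 0.5
#' (fixed for 10 epochs, then adapted in \[0.3, 0.5\] by the 5-epoch
#' validation trend), temperature from the model config, and the
#' grid-search-optimal augmentation (`p_mask = 0.15`, `eta = 0.01`).
#'
#' @param epochs maximum epochs.
#' @param batch_size mini-batch size N (the contrastive batch holds 2N
#'   views).
#' @param base_lr peak Adam learning rate.
#' @param patience early-stopping patience in epochs.
#' @param seed master seed controlling shuffling, dropout, masking and
#'   noise; fixing it reproduces the full history.
#' @param augment an [augmentation_config()].
#' @param lambda_init,lambda_step,lambda_window,lambda_warmup adaptive
#'   multi-task weighting controls (see [update_lambda()]).
#' @param cls_input `"clean"` computes the classification loss on the
#'   unaugmented forward pass (default); `"augmented"` averages it over
#'   the two augmented views.
#' @param schedule `"joint"` optimizes `L_cls + lambda * L_cont` in a
#'   single stage (default); `"two_stage"` first pretrains with the
#'   contrastive loss alone for `pretrain_epochs`, then trains the
#'   classifier with the contrastive term.
#' @param pretrain_epochs epochs of contrastive-only pretraining in
#'   two-stage mode.
#' @param val_frac validation fraction split off the training set when no
#'   validation set is supplied.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, base_lr = 1e-3,
                         patience = 15L, seed = 1L,
                         augment = augmentation_config(),
                         lambda_init = 0.5, lambda_step = 0.05,
                         lambda_window = 5L, lambda_warmup = 10L,
                         cls_input = c("clean", "augmented"),
                         schedule = c("joint", "two_stage"),
                         pretrain_epochs = 10L, val_frac = 0.15) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 patience = as.integer(patience), seed = as.integer(seed),
                 augment = augment, lambda_init = lambda_init,
                 lambda_step = lambda_step,
                 lambda_window = as.integer(lambda_window),
                 lambda_warmup = as.integer(lambda_warmup),
                 cls_input = match.arg(cls_input),
                 schedule = match.arg(schedule),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 val_frac = val_frac),
            class = "train_config")
}

adam_new <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  params
}

accumulate_grads <- function(acc, g) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

# Features for a record batch: token-id matrix (branch 1) and CGR states
# (branch 2), computed once per dataset.
prepare_features <- function(records, config) {
  list(ids = if (config$use_branch1) tokenize_batch(records, config$k) else NULL,
       Xe = if (config$use_branch2) cgr_encode_batch(records) else NULL,
       y = record_labels(records))
}

interleave_rows <- function(A, B) {
  Z <- matrix(0, 2L * nrow(A), ncol(A))
  Z[seq(1L, nrow(Z), 2L), ] <- A
  Z[seq(2L, nrow(Z), 2L), ] <- B
  Z
}

# One optimization step on a mini-batch; returns losses, grads and the
# model with updated batch-norm state.
train_step <- function(model, ids, Xe, y, lambda, cfgT, stage = "joint") {
  cfg <- model$config
  B <- length(y)
  trainable_emb <- cfg$use_branch1 && model$backend$trainable
  X_flat <- if (cfg$use_branch1) {
    embed_ids_flat(ids, model$backend$E)
  } else NULL
  grads <- list()
  dX_total <- if (cfg$use_branch1) X_flat * 0 else NULL
  cls_loss <- NULL
  cont_loss <- NULL

  do_cls <- stage != "pretrain"
  do_cont <- cfg$use_contrastive && stage != "cls_only"

  if (do_cls && cfgT$cls_input == "clean") {
    enc <- encoder_fwd_batch(model, X_flat, Xe, B, train = TRUE)
    model <- enc$model
    clf <- classifier_fwd(model, enc$h, train = TRUE)
    Y <- cbind(1 - y, y)
    cls_loss <- cross_entropy_loss(clf$probs, y)
    dlogits <- (clf$probs - Y) / B
    cb <- classifier_bwd(model, dlogits, clf$cache)
    grads <- accumulate_grads(grads, cb$grads)
    eb <- encoder_bwd_batch(model, cb$dh, enc$cache)
    grads <- accumulate_grads(grads, eb$grads)
    if (!is.null(eb$dX)) dX_total <- dX_total + eb$dX
  }

  if (do_cont || (do_cls && cfgT$cls_input == "augmented")) {
    views <- lapply(1:2, function(i) {
      out <- list()
      if (cfg$use_branch1) {
        M <- if (cfgT$augment$granularity == "token") {
          sample_mask(c(nrow(X_flat), 1L), cfgT$augment$p_mask)
        } else {
          sample_mask(dim(X_flat), cfgT$augment$p_mask)
        }
        out$X <- mask_features(X_flat, M)
        out$M <- M
      }
      if (cfg$use_branch2) out$Xe <- add_noise(Xe, cfgT$augment$eta)
      out
    })
    encs <- lapply(views, function(v) {
      encoder_fwd_batch(model, v$X, v$Xe, B, train = TRUE)
    })
    model <- encs[[2]]$model
    dh_views <- list(matrix(0, B, cfg$h_dim), matrix(0, B, cfg$h_dim))

    if (do_cont) {
      projs <- lapply(encs, function(e) projection_fwd(model, e$h, train = TRUE))
      Zq <- projs[[1]]$z; Zk <- projs[[2]]$z
      Z <- interleave_rows(Zq, Zk)
      nt <- ntxent_loss_grad(Z, cfg$tau)
      cont_loss <- nt$loss
      w <- if (stage == "pretrain") 1 else lambda
      dZq <- nt$dZ[seq(1L, 2L * B, 2L), , drop = FALSE] * w
      dZk <- nt$dZ[seq(2L, 2L * B, 2L), , drop = FALSE] * w
      pb1 <- projection_bwd(model, dZq, projs[[1]]$cache)
      pb2 <- projection_bwd(model, dZk, projs[[2]]$cache)
      grads <- accumulate_grads(grads, pb1$grads)
      grads <- accumulate_grads(grads, pb2$grads)
      dh_views[[1]] <- dh_views[[1]] + pb1$dh
      dh_views[[2]] <- dh_views[[2]] + pb2$dh
    }

    if (do_cls && cfgT$cls_input == "augmented") {
      Y <- cbind(1 - y, y)
      cls_parts <- numeric(2)
      for (i in 1:2) {
        clf <- classifier_fwd(model, encs[[i]]$h, train = TRUE)
        cls_parts[i] <- cross_entropy_loss(clf$probs, y)
        dlogits <- (clf$probs - Y) / (2 * B)
        cb <- classifier_bwd(model, dlogits, clf$cache)
        grads <- accumulate_grads(grads, cb$grads)
        dh_views[[i]] <- dh_views[[i]] + cb$dh
      }
      cls_loss <- mean(cls_parts)
    }

    for (i in 1:2) {
      if (!isTRUE(any(dh_views[[i]] != 0))) next
      eb <- encoder_bwd_batch(model, dh_views[[i]], encs[[i]]$cache)
      grads <- accumulate_grads(grads, eb$grads)
      if (!is.null(eb$dX)) {
        dX_total <- dX_total + mask_features(eb$dX, views[[i]]$M)
      }
    }
  }

  if (trainable_emb && !is.null(dX_total)) {
    ids_vec <- as.vector(ids)
    agg <- rowsum(dX_total, ids_vec)
    dE <- matrix(0, nrow(model$backend$E), ncol(model$backend$E))
    dE[as.integer(rownames(agg)), ] <- agg
    grads$E <- dE
  }

  total <- (if (is.null(cls_loss)) 0 else cls_loss) +
    (if (is.null(cont_loss)) 0 else {
      if (stage == "pretrain") cont_loss else lambda * cont_loss
    })
  list(model = model, grads = grads,
       cls = if (is.null(cls_loss)) NA_real_ else cls_loss,
       cont = if (is.null(cont_loss)) NA_real_ else cont_loss,
       total = total)
}

# Eval-mode forward over a feature set; returns modified-site probability.
predict_from_features <- function(model, feats, batch_size = 256L) {
  n <- length(feats$y)
  out <- numeric(n)
  for (start in seq(1L, n, batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    B <- length(idx)
    Xf <- if (model$config$use_branch1) {
      embed_ids_flat(feats$ids[idx, , drop = FALSE], model$backend$E)
    } else NULL
    Xe <- if (model$config$use_branch2) {
      feats$Xe[idx, , drop = FALSE]
    } else NULL
    enc <- encoder_fwd_batch(model, Xf, Xe, B, train = FALSE)
    out[idx] <- classifier_fwd(model, enc$h, train = FALSE)$probs[, 2]
  }
  out
}

#' Predict modification probabilities for sequence records
#'
#' @param model a trained [mv_model()].
#' @param records list of [sequence_record()] at the model's window
#'   length.
#' @param batch_size internal evaluation batch size.
#' @return numeric vector of modified-site probabilities.
#' @export
predict_proba <- function(model, records, batch_size = 256L) {
  stopifnot(inherits(model, "mv_model"))
  records <- lapply(records, function(r) {
    if (nchar(r$seq) < model$config$L0) {
      r$seq <- pad_sequence(r$seq, model$config$L0)
    }
    r
  })
  feats <- prepare_features(records, model$config)
  predict_from_features(model, feats, batch_size)
}

#' Train the multi-view contrastive classifier
#'
#' Each step draws two independently augmented views per sample, computes
#' the NT-Xent contrastive loss on their projections and the
#' cross-entropy loss on the clean forward pass, and optimizes
#' `L_cls + lambda * L_cont` with Adam under the warm-up/decay schedule.
#' Validation accuracy drives both the adaptive lambda and early stopping
#' (patience `config$patience`); the weights from the best-validation
#' epoch are restored on termination.
#'
#' @param model an [mv_model()].
#' @param train_records,val_records lists of [sequence_record()]; when
#'   `val_records` is NULL a stratified `val_frac` split is carved from
#'   the training set.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-epoch weights), `history` (per-epoch
#'   data frame: epoch, lr, lambda, train losses, val accuracy) and
#'   `best_epoch`.
#' @export
train_model <- function(model, train_records, val_records = NULL,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "mv_model"), length(train_records) > 0)
  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_restore(old_seed), add = TRUE)
  set.seed(config$seed)

  if (is.null(val_records)) {
    y <- record_labels(train_records)
    val_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
      sample(ix, max(1L, round(length(ix) * config$val_frac)))
    }))
    val_records <- train_records[val_idx]
    train_records <- train_records[-val_idx]
  }
  tr <- prepare_features(train_records, model$config)
  va <- prepare_features(val_records, model$config)
  n <- length(tr$y)
  opt <- adam_new()
  state <- training_state(lambda = config$lambda_init,
                          window = config$lambda_window,
                          step = config$lambda_step,
                          warmup_epochs = config$lambda_warmup)
  best <- list(acc = -Inf, epoch = 0L, params = NULL, E = NULL, bn = NULL)
  wait <- 0L
  hist <- list()

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch - 1L, config$base_lr)
    stage <- if (config$schedule == "two_stage") {
      if (epoch <= config$pretrain_epochs) "pretrain" else "joint"
    } else "joint"
    perm <- sample.int(n)
    ep_cls <- 0; ep_cont <- 0; ep_tot <- 0; nb <- 0L
    for (start in seq(1L, n, config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next
      st <- train_step(model,
                       if (!is.null(tr$ids)) tr$ids[idx, , drop = FALSE] else NULL,
                       if (!is.null(tr$Xe)) tr$Xe[idx, , drop = FALSE] else NULL,
                       tr$y[idx], state$lambda, config, stage)
      if (!is.finite(st$total)) {
        stop(sprintf(
          "training diverged at epoch %d (non-finite loss: cls=%g cont=%g); lower base_lr",
          epoch, st$cls, st$cont))
      }
      model <- st$model
      model$params <- adam_step(opt, model$params, st$grads[names(st$grads) != "E"], lr)
      if (!is.null(st$grads$E)) {
        upd <- adam_step(opt, list(E = model$backend$E), st$grads["E"], lr)
        model$backend$E <- upd$E
      }
      ep_cls <- ep_cls + (if (is.na(st$cls)) 0 else st$cls)
      ep_cont <- ep_cont + (if (is.na(st$cont)) 0 else st$cont)
      ep_tot <- ep_tot + st$total
      nb <- nb + 1L
    }
    val_p <- predict_from_features(model, va)
    val_acc <- mean((val_p >= 0.5) == (va$y == 1))
    state$epoch <- epoch
    state$val_acc_history <- c(state$val_acc_history, val_acc)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                lambda = state$lambda,
                                train_total = ep_tot / max(nb, 1L),
                                train_cls = ep_cls / max(nb, 1L),
                                train_cont = ep_cont / max(nb, 1L),
                                val_acc = val_acc)
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.2e  lambda %.2f  loss %.4f (cls %.4f cont %.4f)  val acc %.4f",
        epoch, lr, state$lambda, ep_tot / max(nb, 1L),
        ep_cls / max(nb, 1L), ep_cont / max(nb, 1L), val_acc))
    }
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = epoch, params = model$params,
                   E = model$backend$E, bn = model$bn_state)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
    state <- update_lambda(state)
  }

  if (!is.null(best$params)) {
    model$params <- best$params
    model$backend$E <- best$E
    model$bn_state <- best$bn
  }
  list(model = model, history = do.call(rbind, hist), best_epoch = best$epoch)
}

#' Save a model as a serialized archive with a JSON architecture sidecar
#'
#' @param model an [mv_model()].
#' @param path output path for the parameter archive; a `.json` sidecar
#'   recording the architecture config and seeds is written next to it.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mv_model"))
  saveRDS(model, path)
  side <- list(config = unclass(model$config),
               backend = list(type = model$backend$type, k = model$backend$k,
                              d = model$backend$d, seed = model$backend$seed))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path path to the parameter archive.
#' @return an [mv_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model archive not found: %s", path))
  model <- readRDS(path)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path)
    if (!identical(as.integer(side$config$k), model$config$k)) {
      stop("sidecar architecture config does not match the archive")
    }
  }
  stopifnot(inherits(model, "mv_model"))
  model
}
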