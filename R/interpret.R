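# Interpretability profiles: which window positions drive the
# modified-site probability.

# dlogits for the positive-class probability p2 of a softmax pair:
# d p2 / d logits = (-p1*p2, p2*(1-p2)).
.pos_prob_dlogits <- function(probs) {
  cbind(-probs[, 1] * probs[, 2], probs[, 2] * (1 - probs[, 2]))
}

#' Gradient-based per-position importance profile
#'
#' Differentiates the positive-class probability with respect to the
#' model's input features — the token embedding matrix for the k-mer view
#' (tokens are discrete, so the embedding is the differentiable input)
#' and the CGR state vector for the auxiliary view — and aggregates
#' absolute gradients onto nucleotide positions. A k-mer token's gradient
#' magnitude is credited to every window position the k-mer covers;
#' `[CLS]`/`[SEP]` brackets carry no position. The result is averaged
#' over samples.
#'
#' @param model a trained [mv_model()].
#' @param records list of [sequence_record()].
#' @return list with `profile` (length `L0`, mean absolute gradient per
#'   position) and `per_sample` (samples x `L0` matrix, heatmap form).
#' @export
gradient_importance <- function(model, records) {
  stopifnot(inherits(model, "mv_model"))
  cfg <- model$config
  feats <- prepare_features(records, cfg)
  n <- length(records)
  L0 <- nchar(records[[1]]$seq)
  per_sample <- matrix(0, n, L0)
  bs <- 128L
  for (start in seq(1L, n, bs)) {
    idx <- start:min(start + bs - 1L, n)
    B <- length(idx)
    Xf <- if (cfg$use_branch1) {
      embed_ids_flat(feats$ids[idx, , drop = FALSE], model$backend$E)
    } else NULL
    Xe <- if (cfg$use_branch2) feats$Xe[idx, , drop = FALSE] else NULL
    enc <- encoder_fwd_batch(model, Xf, Xe, B, train = FALSE)
    clf <- classifier_fwd(model, enc$h, train = FALSE)
    cb <- classifier_bwd(model, .pos_prob_dlogits(clf$probs), clf$cache)
    eb <- encoder_bwd_batch(model, cb$dh, enc$cache)
    contrib <- matrix(0, B, L0)
    if (!is.null(eb$dX)) {
      T1 <- nrow(eb$dX) %/% B
      tok_mag <- matrix(rowSums(abs(eb$dX)), B, T1)  # (b, t) layout
      k <- cfg$k
      for (t in 2L:(T1 - 1L)) {        # interior k-mer tokens
        span <- (t - 1L):(t - 2L + k)
        span <- span[span <= L0]
        contrib[, span] <- contrib[, span] + tok_mag[, t]
      }
    }
    if (!is.null(eb$dXe)) contrib <- contrib + abs(eb$dXe)
    per_sample[idx, ] <- contrib
  }
  list(profile = colMeans(per_sample), per_sample = per_sample)
}

#' Perturbation-based per-position importance profile
#'
#' Importance of position p is the mean absolute change in the
#' positive-class score when the nucleotide at p is substituted, averaged
#' over the three alternative bases and over samples. Gap (padding)
#' positions carry no sequence identity and are not perturbed.
#'
#' @param model a trained [mv_model()], or any scoring function mapping a
#'   list of records to numeric scores.
#' @param records list of [sequence_record()].
#' @return list with `profile` (length `L0`) and `per_sample`
#'   (samples x `L0`).
#' @export
perturbation_importance <- function(model, records) {
  scorer <- if (inherits(model, "mv_model")) {
    function(recs) predict_proba(model, recs)
  } else if (is.function(model)) {
    model
  } else stop("model must be an mv_model or a scoring function")
  n <- length(records)
  L0 <- nchar(records[[1]]$seq)
  base_scores <- scorer(records)
  chars <- do.call(rbind, lapply(records, function(r) {
    strsplit(r$seq, "", fixed = TRUE)[[1]]
  }))
  chars[chars == "T"] <- "U"
  delta <- matrix(0, n, L0)
  counts <- matrix(0, n, L0)
  for (p in seq_len(L0)) {
    for (b in NUC_BASES) {
      affected <- which(chars[, p] != b & chars[, p] != "-")
      if (length(affected) == 0) next
      mutated <- lapply(affected, function(i) {
        s <- chars[i, ]; s[p] <- b
        r <- records[[i]]
        r$seq <- paste0(s, collapse = "")
        r
      })
      d <- abs(scorer(mutated) - base_scores[affected])
      delta[affected, p] <- delta[affected, p] + d
      counts[affected, p] <- counts[affected, p] + 1
    }
  }
  per_sample <- ifelse(counts > 0, delta / pmax(counts, 1), 0)
  list(profile = colMeans(per_sample), per_sample = per_sample)
}

#' Write an importance profile as CSV (position, score)
#' @param profile numeric vector from [gradient_importance()] or
#'   [perturbation_importance()] (`$profile`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance_csv <- function(profile, path) {
  utils::write.csv(data.frame(position = seq_along(profile),
                              score = profile),
                   path, row.names = FALSE)
  invisible(path)
}
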