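# Shared builders for desk-scale fixtures. Everything is generated in
# code; no data files.

rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

tiny_model_config <- function(...) {
  model_config(k = 3, embed_dim = 4, L0 = 12, conv_filters = 6,
               lstm_hidden = 3, attn_dim = 3, proj_hidden = 5,
               proj_dim = 2, clf_dims = c(7, 5, 3), gn_groups = 2,
               seed = 42, ...)
}

tiny_records <- function(n, L = 12, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sequence_record(paste0("s", i), rand_seq(L), i %% 2)
  })
}

# Small but learnable setup for training-loop tests: 15-nt windows with a
# centered 4-mer motif.
small_train_setup <- function(seed = 3, n_pos = 40, epochs = 12,
                              variant = "s_cba_bil") {
  ds <- generate_dataset(
    synthetic_config(n_pos = n_pos, n_neg = n_pos, length = 15,
                     motif = "GGAC", motif_offset = -1, seed = seed),
    test_frac = 0.25)
  mc <- ablation_config(variant, k = 3, embed_dim = 8, L0 = 15,
                        conv_filters = 8, lstm_hidden = 8, attn_dim = 8,
                        proj_hidden = 16, proj_dim = 8,
                        clf_dims = c(16, 8, 4), seed = seed)
  tc <- train_config(epochs = epochs, batch_size = 16, seed = seed)
  list(ds = ds, mc = mc, tc = tc)
}

# Literal per-position IFS recursion, independent of the production
# vectorized path.
cgr_oracle <- function(seq, alpha = 0.5) {
  verts <- list(A = c(0, 0), C = c(0, 1), G = c(1, 1),
                T = c(1, 0), U = c(1, 0))
  chars <- strsplit(toupper(seq), "")[[1]]
  p <- c(0.5, 0.5)
  out <- matrix(NA_real_, length(chars), 2)
  for (i in seq_along(chars)) {
    if (chars[i] != "-") p <- p + alpha * (verts[[chars[i]]] - p)
    out[i, ] <- p
  }
  out
}

# Exhaustive pairwise-concordance AUROC (ties count one half).
auroc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Constant-output probe: a model whose classifier weights are all zero
# emits probability 0.5 regardless of input.
constant_output_model <- function(cfg = tiny_model_config()) {
  m <- mv_model(cfg)
  for (i in 1:4) {
    m$params[[sprintf("f_W%d", i)]][] <- 0
    m$params[[sprintf("f_b%d", i)]][] <- 0
  }
  m
}
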