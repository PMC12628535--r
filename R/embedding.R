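#' Configure the k-mer variant of the token embedding backend
#'
#' Chooses the k-mer size of the primary-view tokenizer/vocabulary. The
#' default is `k = 6`, the variant with the strongest downstream
#' performance among k = 3..6.
#'
#' @param k k-mer size in 3..6 (default 6).
#' @return list with `k`, `vocab_size` (`4^k + 5`) and `tokens_per_seq`, a
#'   function of the window length giving `L0 - k + 3`.
#' @export
select_kmer_variant <- function(k = 6L) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 3L || k > 6L) {
    stop("unsupported k-mer size; k must be in {3,4,5,6}")
  }
  list(k = k,
       vocab_size = 4L^k + 5L,
       tokens_per_seq = function(L0) L0 - k + 3L)
}

#' Trainable lookup-table embedding backend
#'
#' A plain embedding matrix (`vocab_size x d`) with rows drawn from a
#' seeded uniform Glorot scheme. Rows are shared across positions (weight
#' tying by token id) and are trained end-to-end with the encoder. This is
#' the default backend; a frozen pretrained table can be loaded with
#' [pretrained_backend()].
#'
#' @param k k-mer size (default 6).
#' @param d embedding dimension (default 32; set 768 for parity with
#'   transformer-scale features).
#' @param seed RNG seed for initialization.
#' @return an `embedding_backend` (type "lookup", trainable).
#' @export
lookup_backend <- function(k = 6L, d = 32L, seed = 1L) {
  variant <- select_kmer_variant(k)
  V <- variant$vocab_size
  old <- .Random.seed_get()
  set.seed(seed)
  lim <- sqrt(6 / (V + d))
  E <- matrix(stats::runif(V * d, -lim, lim), V, d)
  .Random.seed_restore(old)
  structure(list(type = "lookup", k = variant$k, d = as.integer(d),
                 E = E, trainable = TRUE, seed = as.integer(seed)),
            class = "embedding_backend")
}

#' Frozen pretrained per-token embedding backend
#'
#' Loads a frozen per-token embedding table exported from a pretrained DNA
#' language model. The file must be a whitespace/TSV numeric table with
#' `4^k + 5` rows (vocabulary order of [build_vocab()]) and one column per
#' embedding dimension (768 for transformer-scale models). The table is
#' used in feature-extractor mode: rows are never updated during training.
#'
#' @param path path to the weights table.
#' @param k k-mer size the table was built for (default 6).
#' @return an `embedding_backend` (type "pretrained", frozen).
#' @export
pretrained_backend <- function(path, k = 6L) {
  variant <- select_kmer_variant(k)
  if (missing(path) || is.null(path) || !file.exists(path)) {
    stop(paste0(
      "pretrained embedding weights not found",
      if (!missing(path) && !is.null(path)) sprintf(" at '%s'", path) else "",
      "; either supply an exported per-token weights table or use the ",
      "trainable lookup backend: lookup_backend(k = ", variant$k, ")"))
  }
  E <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(E) != variant$vocab_size) {
    stop(sprintf("weights table has %d rows; expected %d (= 4^%d + 5)",
                 nrow(E), variant$vocab_size, variant$k))
  }
  storage.mode(E) <- "double"
  dimnames(E) <- NULL
  structure(list(type = "pretrained", k = variant$k, d = ncol(E),
                 E = E, trainable = FALSE, seed = NA_integer_),
            class = "embedding_backend")
}

#' Embed a token sequence into the primary-view feature matrix
#'
#' @param tokens a `token_sequence` from [kmerize()].
#' @param backend an `embedding_backend`.
#' @return An `embedded_sequence`: list with `X` (tokens x d matrix) and
#'   `d`.
#' @export
embed_tokens <- function(tokens, backend) {
  stopifnot(inherits(tokens, "token_sequence"),
            inherits(backend, "embedding_backend"))
  if (tokens$k != backend$k) {
    stop(sprintf("token k (%d) does not match backend k (%d)",
                 tokens$k, backend$k))
  }
  ids <- tokens$ids
  if (any(ids < 1L) || any(ids > nrow(backend$E))) {
    stop("token id out of range for the backend vocabulary")
  }
  structure(list(X = backend$E[ids, , drop = FALSE], d = ncol(backend$E)),
            class = "embedded_sequence")
}

# Flat (B*T) x d embedding of an id matrix; row r = b + (t-1)*B matches the
# column-major flattening used throughout the network code.
embed_ids_flat <- function(ids_mat, E) {
  E[as.vector(ids_mat), , drop = FALSE]
}

# Save/restore the global RNG state so seeded initializers do not disturb
# the caller's random stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
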