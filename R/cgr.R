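# Chaos-game representation: vertex assignment A=(0,0), C=(0,1), G=(1,1),
# T/U=(1,0); iterated function system p_i = p_{i-1} + alpha*(v - p_{i-1}).
CGR_VERTICES <- matrix(
  c(0, 0,
    0, 1,
    1, 1,
    1, 0,
    1, 0),
  ncol = 2, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T", "U"), c("x", "y"))
)

#' Chaos-game-representation coordinate trace of a sequence
#'
#' Maps a nucleotide sequence into the unit square by the iterated function
#' system `p_i = p_{i-1} + alpha * (v_{x_i} - p_{i-1})`, starting from the
#' centroid `p_0 = (0.5, 0.5)` (not emitted) with contraction ratio
#' `alpha = 0.5`. Vertices: A = (0,0), C = (0,1), G = (1,1), T = (1,0); U
#' shares T's vertex. Because the map is a contraction, the influence of a
#' position on later coordinates decays as `alpha^distance` — nearby
#' sequence context dominates each coordinate.
#'
#' Gap characters (`-`, terminal padding) carry no sequence identity: the
#' coordinate update is skipped (`p_i = p_{i-1}`), so padded positions do
#' not fabricate geometry.
#'
#' @param seq character sequence over `{A,C,G,U,T,-}`.
#' @param alpha contraction ratio of the IFS (default 0.5).
#' @return A `cgr_trace`: list with `coords` (n x 2 matrix in the unit
#'   square), `states` (numeric vector, see [cgr_states()]), and `alpha`.
#' @export
cgr_trace <- function(seq, alpha = 0.5) {
  seq <- toupper(seq)
  validate_alphabet(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0) stop("cannot compute a CGR trace of an empty sequence")
  coords <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  p <- c(0.5, 0.5)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch != "-") {
      v <- CGR_VERTICES[ch, ]
      p <- p + alpha * (v - p)
    }
    coords[i, ] <- p
  }
  structure(list(coords = coords,
                 states = unname(coords[, 2] - coords[, 1]),
                 alpha = alpha),
            class = "cgr_trace")
}

#' Scalar CGR state vector of a trace
#'
#' Collapses each 2-D CGR coordinate to the scalar
#' `State_i = p_i^y - p_i^x` (vertical minus horizontal component),
#' yielding the one-dimensional per-position feature channel consumed by
#' the auxiliary-view BiLSTM branch. States lie in `[-1, 1]`.
#'
#' @param trace a `cgr_trace` from [cgr_trace()].
#' @return numeric vector of length equal to the sequence length.
#' @export
cgr_states <- function(trace) {
  stopifnot(inherits(trace, "cgr_trace"))
  unname(trace$coords[, 2] - trace$coords[, 1])
}

#' @export
print.cgr_trace <- function(x, ...) {
  cat(sprintf("<cgr_trace> %d positions, alpha=%g\n", nrow(x$coords), x$alpha))
  invisible(x)
}

#' Encode a batch of records into the CGR state feature matrix
#'
#' Stacks per-record scalar state vectors into an `n x L0` matrix — one
#' single-channel feature per sequence position (feature dimension
#' `D = 1`). All records must share a common padded length.
#'
#' @param records list of [sequence_record()] padded to a common length.
#' @return numeric matrix (`n_records x L0`); zero-row matrix with `L0 = 0`
#'   columns for an empty batch.
#' @export
cgr_encode_batch <- function(records) {
  if (length(records) == 0) return(matrix(numeric(0), nrow = 0, ncol = 0))
  lens <- vapply(records, function(r) nchar(r$seq), 0L)
  if (length(unique(lens)) > 1) {
    stop("records have ragged lengths; pad to a common window length first")
  }
  t(vapply(records, function(r) cgr_trace(r$seq)$states, numeric(lens[1])))
}

#' Write a CGR trace as CSV (position, x, y, state) for inspection
#' @param trace a `cgr_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgr_csv <- function(trace, path) {
  df <- data.frame(position = seq_len(nrow(trace$coords)),
                   x = trace$coords[, 1], y = trace$coords[, 2],
                   state = trace$states)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
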