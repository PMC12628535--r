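RNA_ALPHABET <- c("A", "C", "G", "U", "T", "-")
NUC_BASES <- c("A", "C", "G", "U")
SPECIAL_TOKENS <- c("[CLS]", "[PAD]", "[UNK]", "[SEP]", "[MASK]")

.vocab_cache <- new.env(parent = emptyenv())

#' Create a labeled sequence record
#'
#' A `sequence_record` holds one fixed-length RNA window centered on a
#' candidate modification site, together with a binary label (1 = modified,
#' 0 = unmodified). Sequences are uppercased and validated against the
#' alphabet `A, C, G, U, T, -` (the gap character `-` is used for terminal
#' padding of windows shorter than the standard length).
#'
#' @param id character identifier.
#' @param seq character sequence over `{A,C,G,U,T,-}`.
#' @param label integer 0 or 1.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, seq, label) {
  seq <- toupper(as.character(seq))
  validate_alphabet(seq, id)
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) {
    stop(sprintf("record '%s': label must be 0 or 1, got %s", id, label))
  }
  structure(list(id = as.character(id), seq = seq, label = label),
            class = "sequence_record")
}

validate_alphabet <- function(seq, id = "<unnamed>") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), RNA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("record '%s': illegal character(s) %s (alphabet is %s)",
                 id, paste(sQuote(bad), collapse = ", "),
                 paste(RNA_ALPHABET, collapse = "")))
  }
  invisible(TRUE)
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s [label=%d] %s\n", x$id, x$label, x$seq))
  invisible(x)
}

#' Read labeled sequences from a FASTA file
#'
#' Labels are encoded in the FASTA headers as a `|0` / `|1` suffix
#' (e.g. `>chr1_site42|1`), or supplied separately through `labels`
#' (recycled against records in file order).
#'
#' @param path path to a FASTA file.
#' @param labels optional integer vector of labels overriding any header
#'   encoding; must match the number of entries.
#' @param default_label label assigned to entries whose header carries no
#'   suffix (default NULL: an unlabeled header is an error). Use 0 when
#'   scoring unlabeled sequences.
#' @return list of [sequence_record()] objects.
#' @export
read_fasta <- function(path, labels = NULL, default_label = NULL) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s", path,
                                     conditionMessage(e)))
  )
  if (length(set) == 0) return(list())
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (is.null(labels)) {
    parts <- regmatches(headers, regexec("^(.*)\\|([01])$", headers))
    ids <- character(length(headers))
    labels <- integer(length(headers))
    for (i in seq_along(headers)) {
      if (length(parts[[i]]) == 3) {
        ids[i] <- parts[[i]][2]
        labels[i] <- as.integer(parts[[i]][3])
      } else if (!is.null(default_label)) {
        ids[i] <- headers[i]
        labels[i] <- as.integer(default_label)
      } else {
        stop(sprintf(
          "FASTA header '%s' carries no '|0'/'|1' label suffix; pass labels= explicitly",
          headers[i]))
      }
    }
  } else {
    if (length(labels) != length(set)) {
      stop("labels must have one entry per FASTA record")
    }
    ids <- headers
  }
  mapply(sequence_record, ids, seqs, labels, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read labeled sequences from a two-column TSV (label TAB sequence)
#'
#' @param path path to a tab-separated file with columns label, sequence
#'   (no header).
#' @return list of [sequence_record()] objects with ids `seq1, seq2, ...`.
#' @export
read_label_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("TSV file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("label", "seq"),
                          colClasses = c("integer", "character"))
  if (nrow(df) == 0) return(list())
  mapply(sequence_record, paste0("seq", seq_len(nrow(df))), df$seq, df$label,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to FASTA (labels as `|0`/`|1` header suffix)
#' @param records list of [sequence_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, function(r) sprintf("%s|%d", r$id, r$label), "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write records to a two-column TSV (label TAB sequence)
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_label_tsv <- function(records, path) {
  df <- data.frame(label = vapply(records, `[[`, 0L, "label"),
                   seq = vapply(records, `[[`, "", "seq"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pad a sequence to a fixed window length with terminal gap characters
#'
#' Windows shorter than the standardized length are extended by appending
#' `-` at the 3' terminus; longer inputs are an error (no silent
#' truncation).
#'
#' @param seq character sequence.
#' @param target_len target window length (default 41 nt).
#' @return character of exactly `target_len` characters.
#' @export
pad_sequence <- function(seq, target_len = 41L) {
  n <- nchar(seq)
  if (n > target_len) {
    stop(sprintf("sequence length %d exceeds target length %d", n, target_len))
  }
  paste0(seq, strrep("-", target_len - n))
}

#' Build the k-mer vocabulary for a genomic language model
#'
#' The vocabulary comprises five special tokens (`[CLS]`, `[PAD]`, `[UNK]`,
#' `[SEP]`, `[MASK]`) at fixed reserved indices 1..5 followed by all `4^k`
#' DNA k-mers in lexicographic order (A < C < G < T), for a total size of
#' `4^k + 5`. The mapping is deterministic: the same `k` always yields an
#' identical vocabulary.
#'
#' @param k k-mer size, one of 3, 4, 5, 6.
#' @return named integer vector mapping token string to 1-based id, with
#'   attributes `k` and `size`.
#' @export
build_vocab <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 3L || k > 6L) {
    stop("k must be a single integer in {3,4,5,6}")
  }
  key <- as.character(k)
  if (!is.null(.vocab_cache[[key]])) return(.vocab_cache[[key]])
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reorder for lexicographic
  kmers <- sort(apply(grid, 1L, paste0, collapse = ""))
  toks <- c(SPECIAL_TOKENS, kmers)
  vocab <- stats::setNames(seq_along(toks), toks)
  attr(vocab, "k") <- k
  attr(vocab, "size") <- length(toks)
  .vocab_cache[[key]] <- vocab
  vocab
}

#' Tokenize a sequence into overlapping k-mers with [CLS]/[SEP] brackets
#'
#' A window of length `L0` is decomposed into `L0 - k + 1` overlapping
#' k-mers (sliding window, stride 1), bracketed by `[CLS]` and `[SEP]` for
#' a token count of `L0 - k + 3`. Uracil is mapped to thymine for
#' vocabulary lookup (the k-mer vocabulary is DNA-alphabet); any k-mer
#' containing a gap character maps to `[UNK]`.
#'
#' @param seq character sequence over `{A,C,G,U,T,-}`.
#' @param k k-mer size in 3..6.
#' @return A `token_sequence`: list with `tokens` (character), `ids`
#'   (integer indices into [build_vocab()]), and `k`.
#' @export
kmerize <- function(seq, k) {
  vocab <- build_vocab(k)
  seq <- toupper(seq)
  validate_alphabet(seq)
  L0 <- nchar(seq)
  if (L0 < k) stop(sprintf("sequence length %d is shorter than k = %d", L0, k))
  n_kmers <- L0 - k + 1L
  starts <- seq_len(n_kmers)
  kmers <- substring(seq, starts, starts + k - 1L)
  gap <- grepl("-", kmers, fixed = TRUE)
  # vocabulary is DNA-alphabet: uracil maps to thymine for id lookup only
  lookup <- chartr("U", "T", kmers)
  kmers[gap] <- "[UNK]"
  lookup[gap] <- "[UNK]"
  tokens <- c("[CLS]", kmers, "[SEP]")
  ids <- unname(vocab[c("[CLS]", lookup, "[SEP]")])
  if (anyNA(ids)) stop("internal error: token missing from vocabulary")
  structure(list(tokens = tokens, ids = ids, k = as.integer(k)),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence> k=%d, %d tokens: %s ...\n", x$k,
              length(x$tokens), paste(utils::head(x$tokens, 5), collapse = " ")))
  invisible(x)
}

# Token id matrix (n_records x n_tokens) for a batch of equal-length records.
tokenize_batch <- function(records, k) {
  ids <- lapply(records, function(r) kmerize(r$seq, k)$ids)
  lens <- lengths(ids)
  if (length(unique(lens)) > 1) {
    stop("records have ragged lengths; pad to a common window length first")
  }
  do.call(rbind, ids)
}

record_labels <- function(records) {
  vapply(records, `[[`, 0L, "label")
}
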