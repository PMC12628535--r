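# Synthetic planted-motif datasets: balanced classes, fixed 41-nt
# windows, a positional motif distinguishing positives — the structure of
# curated methylation-site benchmarks, desk-scale.

IUPAC_RNA <- list(A = "A", C = "C", G = "G", U = "U", T = "U",
                  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
                  W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
                  B = c("C", "G", "U"), D = c("A", "G", "U"),
                  H = c("A", "C", "U"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "U"))

#' Synthetic dataset configuration
#'
#' Defaults emulate a sample-limited methylation benchmark: balanced
#' 1:1 classes, 41-nt windows, uniform base composition, and a fully
#' penetrant 5-mer motif (`GGACU`, the m6A-like consensus) planted at the
#' window center. 400 positives + 400 negatives with a 0.25 test fraction
#' yields the 600-train / 200-test split used throughout the package's
#' end-to-end checks.
#'
#' @param n_pos,n_neg class sizes (train + test combined).
#' @param length window length (default 41).
#' @param motif IUPAC-degenerate motif string planted in positives.
#' @param motif_offset start offset of the motif relative to the window
#'   center (0 places the motif's first base at the center).
#' @param insertion_prob fraction of positives carrying the motif; 0
#'   gives label-free null data.
#' @param background per-base composition (named A/C/G/U, normalized).
#' @param seed RNG seed; the same config reproduces the same dataset.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_pos = 400L, n_neg = 400L, length = 41L,
                             motif = "GGACU", motif_offset = -2L,
                             insertion_prob = 1,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, U = 0.25),
                             seed = 1L) {
  motif <- toupper(motif)
  mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (!all(mchars %in% names(IUPAC_RNA))) {
    stop("motif must be an IUPAC nucleotide string")
  }
  if (insertion_prob < 0 || insertion_prob > 1) {
    stop("insertion_prob must lie in [0, 1]")
  }
  center <- (as.integer(length) + 1L) %/% 2L
  start <- center + as.integer(motif_offset)
  if (start < 1L || start + nchar(motif) - 1L > length) {
    stop(sprintf("motif does not fit: start %d, end %d, window %d",
                 start, start + nchar(motif) - 1L, length))
  }
  background <- background / sum(background)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length), motif = motif,
                 motif_offset = as.integer(motif_offset),
                 motif_start = start, insertion_prob = insertion_prob,
                 background = background, seed = as.integer(seed)),
            class = "synthetic_config")
}

.matches_motif <- function(chars, motif_chars, start) {
  span <- chars[start:(start + length(motif_chars) - 1L)]
  all(mapply(function(ch, m) ch %in% IUPAC_RNA[[m]], span, motif_chars))
}

#' Generate a balanced synthetic planted-motif dataset
#'
#' Positives carry a realization of the (possibly degenerate) motif at
#' the planted offset with probability `insertion_prob`; negatives are
#' background-sampled and rejection-sampled to exclude a motif match at
#' that offset (only there — generation stays O(n)). The result is split
#' stratified by class into train and test.
#'
#' @param config a [synthetic_config()].
#' @param test_frac fraction of each class held out as the test split.
#' @return list with `train` and `test` lists of [sequence_record()].
#' @export
generate_dataset <- function(config = synthetic_config(), test_frac = 0.25) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  bases <- names(config$background)
  mchars <- strsplit(config$motif, "", fixed = TRUE)[[1]]
  start <- config$motif_start
  span <- start:(start + length(mchars) - 1L)

  draw_bg <- function() sample(bases, config$length, replace = TRUE,
                               prob = config$background)
  positives <- lapply(seq_len(config$n_pos), function(i) {
    chars <- draw_bg()
    if (stats::runif(1) <= config$insertion_prob) {
      chars[span] <- vapply(mchars, function(m) {
        opts <- IUPAC_RNA[[m]]
        if (length(opts) == 1L) opts else sample(opts, 1L)
      }, "")
    }
    sequence_record(sprintf("pos%04d", i), paste0(chars, collapse = ""), 1L)
  })
  negatives <- lapply(seq_len(config$n_neg), function(i) {
    repeat {
      chars <- draw_bg()
      if (!.matches_motif(chars, mchars, start)) break
    }
    sequence_record(sprintf("neg%04d", i), paste0(chars, collapse = ""), 0L)
  })

  split_class <- function(recs) {
    n_test <- round(length(recs) * test_frac)
    test_idx <- sample(seq_along(recs), n_test)
    list(train = recs[setdiff(seq_along(recs), test_idx)],
         test = recs[test_idx])
  }
  sp <- split_class(positives)
  sn <- split_class(negatives)
  train <- c(sp$train, sn$train)
  test <- c(sp$test, sn$test)
  list(train = train[sample(length(train))],
       test = test[sample(length(test))])
}

#' Worked confusion-matrix fixture for a balanced 86+/86- test split
#'
#' The unique non-negative integer counts consistent with sensitivity
#' 83.72% and specificity 77.91% on a balanced test set of 86 positives
#' and 86 negatives: TP = 72, FN = 14, TN = 67, FP = 19. Used as the
#' desk-checkable worked example for the full metric suite.
#'
#' @return a `confusion_counts` object.
#' @export
worked_confusion_fixture <- function() {
  structure(list(TP = 72L, TN = 67L, FP = 19L, FN = 14L),
            class = "confusion_counts")
}
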