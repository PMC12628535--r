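#' Confusion counts at a decision threshold
#'
#' @param labels binary vector (1 = modified site).
#' @param scores numeric scores or probabilities; predictions are
#'   `score >= threshold`.
#' @param threshold decision threshold (default 0.5).
#' @return a `confusion_counts` list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1 & labels == 1),
                 TN = sum(pred == 0 & labels == 0),
                 FP = sum(pred == 1 & labels == 0),
                 FN = sum(pred == 0 & labels == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

safe_ratio <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' Threshold classification metrics from confusion counts
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy,
#' precision `TP/(TP+FP)`, F1 and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A metric whose
#' denominator vanishes is reported as 0 and listed in the `degenerate`
#' attribute rather than raising, so degenerate cross-validation folds do
#' not abort a run.
#'
#' @param counts a [confusion_counts()].
#' @return a `metric_report` list with Sn, Sp, Acc, Pre, F1, MCC and a
#'   `degenerate` character vector attribute naming flagged metrics.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  flagged <- character(0)
  grab <- function(x, name) {
    if (isTRUE(attr(x, "degenerate"))) flagged <<- c(flagged, name)
    as.numeric(x)
  }
  Sn <- grab(safe_ratio(TP, TP + FN), "Sn")
  Sp <- grab(safe_ratio(TN, TN + FP), "Sp")
  Acc <- grab(safe_ratio(TP + TN, n), "Acc")
  Pre <- grab(safe_ratio(TP, TP + FP), "Pre")
  F1 <- grab(safe_ratio(2 * Pre * Sn, Pre + Sn), "F1")
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  MCC <- grab(safe_ratio(TP * TN - FP * FN, mcc_den), "MCC")
  structure(list(Sn = Sn, Sp = Sp, Acc = Acc, Pre = Pre, F1 = F1, MCC = MCC),
            degenerate = unique(flagged), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> Acc %.4f  Sn %.4f  Sp %.4f  Pre %.4f  F1 %.4f  MCC %.4f\n",
    x$Acc, x$Sn, x$Sp, x$Pre, x$F1, x$MCC))
  deg <- attr(x, "degenerate")
  if (length(deg)) cat("  degenerate (reported 0):", paste(deg, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) identity: the probability that a
#' random positive outscores a random negative, with ties counting one
#' half — exactly the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores.
#' @param labels binary labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("AUROC requires both classes to be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of precision over recall across all score
#' thresholds (recall 0 anchored at the first threshold's precision).
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("AUPRC requires both classes to be present")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  # evaluate at distinct thresholds only (last index of each tied block)
  keep <- c(diff(sc) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  rec <- c(0, rec)
  prec <- c(prec[1], prec)
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Points of the ROC and PR curves
#'
#' @inheritParams auroc
#' @return list of two data frames: `roc` (fpr, tpr) and `pr` (recall,
#'   precision), ordered by decreasing threshold.
#' @export
roc_pr_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  keep <- c(diff(sc) != 0, TRUE)
  tp <- c(0, tp[keep]); fp <- c(0, fp[keep])
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  list(roc = data.frame(fpr = fp / nneg, tpr = tp / npos),
       pr = data.frame(recall = tp / npos,
                       precision = ifelse(tp + fp == 0, 1, tp / (tp + fp))))
}

#' Full evaluation of a model on a labeled test set
#'
#' @param model a trained [mv_model()].
#' @param records test [sequence_record()] list.
#' @param threshold decision threshold for the confusion-based metrics.
#' @return list with `metrics` (a `metric_report`), `auroc`, `auprc`,
#'   `counts`, `scores` and `labels`.
#' @export
evaluate_model <- function(model, records, threshold = 0.5) {
  scores <- predict_proba(model, records)
  labels <- record_labels(records)
  counts <- confusion_counts(labels, scores, threshold)
  list(metrics = classification_metrics(counts),
       auroc = auroc(scores, labels),
       auprc = auprc(scores, labels),
       counts = counts, scores = scores, labels = labels)
}

#' Distribution of AUROC over repeated independent training runs
#'
#' Per-run seeds are derived deterministically from the master seed, so
#' the same master seed reproduces the full distribution.
#'
#' @param train_records,test_records datasets for each run.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()] (its seed is overridden per run).
#' @param n_runs number of independent runs.
#' @param master_seed master seed.
#' @return list with `auroc` (length `n_runs`), `summary` (quantiles) and
#'   `per_run` metric list.
#' @export
repeated_runs <- function(train_records, test_records, model_cfg,
                          train_cfg = train_config(), n_runs = 5L,
                          master_seed = 1L) {
  stopifnot(n_runs >= 1L)
  seeds <- master_seed * 1000L + seq_len(n_runs)
  per_run <- vector("list", n_runs)
  aucs <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    mc <- model_cfg; mc$seed <- seeds[i]
    tc <- train_cfg; tc$seed <- seeds[i]
    fit <- train_model(mv_model(mc), train_records, config = tc)
    ev <- evaluate_model(fit$model, test_records)
    per_run[[i]] <- ev$metrics
    aucs[i] <- ev$auroc
  }
  list(auroc = aucs,
       summary = stats::quantile(aucs, c(0, 0.25, 0.5, 0.75, 1)),
       per_run = per_run)
}

#' Cross-modification transfer matrix of AUROC
#'
#' Trains one model per dataset and evaluates every model on every
#' dataset's test split: entry (i, j) is the AUROC of the model trained
#' on dataset i tested on dataset j. The diagonal equals standard
#' same-type evaluation.
#'
#' @param datasets named list; each element is a list with `train` and
#'   `test` record lists.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @return square numeric matrix (train x test) with dataset names.
#' @export
cross_modification_matrix <- function(datasets, model_cfg,
                                      train_cfg = train_config()) {
  if (length(datasets) < 2L) stop("need at least two datasets")
  nms <- names(datasets)
  if (is.null(nms)) nms <- paste0("set", seq_along(datasets))
  n <- length(datasets)
  M <- matrix(NA_real_, n, n, dimnames = list(train = nms, test = nms))
  for (i in seq_len(n)) {
    fit <- train_model(mv_model(model_cfg), datasets[[i]]$train,
                       config = train_cfg)
    for (j in seq_len(n)) {
      te <- datasets[[j]]$test
      M[i, j] <- auroc(predict_proba(fit$model, te), record_labels(te))
    }
  }
  M
}

#' Welch two-sample t-statistic per representation dimension
#'
#' Compares positive- against negative-class samples for every column of
#' a representation matrix:
#' `t = (mean_pos - mean_neg) / sqrt(s2_pos/n_pos + s2_neg/n_neg)`.
#' Dimensions with zero variance in both groups (undefined statistic) are
#' reported as `NA` and flagged.
#'
#' @param representations numeric matrix (samples x dimensions).
#' @param labels binary labels, both classes with >= 2 samples.
#' @return data frame with `dim`, `t` (positive minus negative), ordered
#'   as input; attribute `top` gives the dims ranked by `|t|`.
#' @export
feature_t_stats <- function(representations, labels) {
  X <- as.matrix(representations)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("each class needs at least two samples")
  }
  A <- X[labels == 1, , drop = FALSE]
  B <- X[labels == 0, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  se2 <- apply(A, 2, stats::var) / na + apply(B, 2, stats::var) / nb
  t <- (colMeans(A) - colMeans(B)) / sqrt(se2)
  t[se2 == 0] <- NA_real_
  out <- data.frame(dim = seq_len(ncol(X)), t = unname(t))
  attr(out, "top") <- out$dim[order(-abs(out$t), na.last = TRUE)]
  out
}
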