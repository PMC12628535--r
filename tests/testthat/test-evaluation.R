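test_that("confusion counts partition the sample at any threshold", {
  lab <- c(1, 1, 1, 0, 0, 0)
  perfect <- confusion_counts(lab, c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3))
  expect_equal(unclass(perfect)[c("TP", "TN", "FP", "FN")],
               list(TP = 3L, TN = 3L, FP = 0L, FN = 0L))

  inverted <- confusion_counts(lab, c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7))
  expect_equal(inverted$TP, 0L)
  expect_equal(inverted$TN, 0L)

  # threshold above every score: everything predicted negative
  allneg <- confusion_counts(lab, c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3),
                             threshold = 1.0)
  expect_equal(allneg$TP + allneg$FP, 0L)
  expect_equal(allneg$TN + allneg$FN, 6L)

  expect_error(confusion_counts(c(1, 0), c(0.5)), "equal length")
  expect_error(confusion_counts(c(1, 2), c(0.5, 0.5)), "binary")
})

test_that("the worked 86+/86- confusion fixture reproduces the printed metric row", {
  counts <- worked_confusion_fixture()
  expect_equal(counts$TP + counts$FN, 86L)
  expect_equal(counts$TN + counts$FP, 86L)
  m <- classification_metrics(counts)
  expect_equal(round(100 * m$Sn, 2), 83.72)
  expect_equal(round(100 * m$Sp, 2), 77.91)
  expect_equal(round(100 * m$Acc, 2), 80.81)
  expect_equal(round(100 * m$Pre, 2), 79.12)
  expect_equal(round(100 * m$F1, 2), 81.36)
  expect_equal(round(100 * m$MCC, 2), 61.73)
})

test_that("metrics agree with an independent recomputation on random data", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    sc <- runif(n)
    pred <- as.integer(sc >= 0.5)
    m <- classification_metrics(confusion_counts(lab, sc))
    expect_equal(m$Acc, mean(pred == lab))
    expect_equal(m$Sn, sum(pred & lab) / sum(lab))
    # MCC equals the phi coefficient of the two binary vectors
    if (stats::sd(pred) > 0) {
      expect_equal(m$MCC, suppressWarnings(stats::cor(pred, lab)),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate counts report zeros with a flag instead of aborting", {
  balanced <- classification_metrics(
    structure(list(TP = 25L, TN = 25L, FP = 25L, FN = 25L),
              class = "confusion_counts"))
  expect_equal(balanced$MCC, 0)
  expect_equal(balanced$Acc, 0.5)

  deg <- classification_metrics(
    structure(list(TP = 0L, TN = 0L, FP = 0L, FN = 5L),
              class = "confusion_counts"))
  expect_equal(deg$Pre, 0)
  expect_true("Pre" %in% attr(deg, "degenerate"))
  expect_true("MCC" %in% attr(deg, "degenerate"))
})

test_that("AUROC matches hand values and the tie convention", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("rank AUROC equals the exhaustive pairwise oracle and pROC", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), 2)  # coarse grid forces ties
    a <- auroc(sc, lab)
    expect_equal(a, auroc_pairwise_oracle(sc, lab), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    lab <- c(1, 1, 0, 0, 1, 0, 1, 0)
    sc <- c(0.8, 0.6, 0.55, 0.3, 0.7, 0.6, 0.2, 0.1)
    expect_equal(auroc(sc, lab),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("AUPRC integrates the PR curve trapezoidally", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # hand-integrated case: scores (0.9, 0.8, 0.7), labels (1, 0, 1)
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               0.5 + 0.5 * (0.5 + 2 / 3) / 2, tolerance = 1e-12)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "both classes")
})

test_that("ROC/PR point sets span the unit interval monotonically", {
  set.seed(34)
  sc <- runif(30); lab <- rbinom(30, 1, 0.5)
  pts <- roc_pr_points(sc, lab)
  expect_true(all(diff(pts$roc$fpr) >= 0))
  expect_true(all(diff(pts$roc$tpr) >= 0))
  expect_equal(utils::tail(pts$roc$tpr, 1), 1)
  expect_equal(utils::tail(pts$pr$recall, 1), 1)
})

test_that("Welch t-statistics match the textbook value and t.test", {
  X <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5), ncol = 1)
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0)
  ts <- feature_t_stats(X, lab)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$t, -1.095445, tolerance = 1e-6)
  expect_equal(ts$t, unname(stats::t.test(X[lab == 1, 1], X[lab == 0, 1])$statistic),
               tolerance = 1e-12)

  set.seed(35)
  M <- matrix(rnorm(40 * 6), 40, 6)
  lab2 <- rep(c(1, 0), each = 20)
  ts2 <- feature_t_stats(M, lab2)
  expect_equal(nrow(ts2), 6)
  for (j in 1:6) {
    expect_equal(ts2$t[j],
                 unname(stats::t.test(M[lab2 == 1, j], M[lab2 == 0, j])$statistic),
                 tolerance = 1e-12)
  }

  # identical distributions: statistics near zero
  same <- matrix(rep(rnorm(20), 2), 40, 1)
  expect_lt(abs(feature_t_stats(same, lab2)$t), 1e-12)

  # zero variance in both groups: flagged sentinel
  flat <- matrix(1, 40, 1)
  expect_true(is.na(feature_t_stats(flat, lab2)$t))
  expect_error(feature_t_stats(M, rep(1, 40)), "at least two")
})
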