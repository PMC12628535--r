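test_that("a fixed master seed reproduces the full training history", {
  su <- small_train_setup(seed = 3, epochs = 6)
  f1 <- train_model(mv_model(su$mc), su$ds$train, config = su$tc)
  f2 <- train_model(mv_model(su$mc), su$ds$train, config = su$tc)
  expect_identical(f1$history, f2$history)
  expect_equal(predict_proba(f1$model, su$ds$test),
               predict_proba(f2$model, su$ds$test))
})

test_that("lambda holds at 0.5 through the warm-up epochs and stays bounded", {
  su <- small_train_setup(seed = 4, epochs = 13)
  fit <- train_model(mv_model(su$mc), su$ds$train, config = su$tc)
  h <- fit$history
  expect_true(all(h$lambda[h$epoch <= 10] == 0.5))
  expect_true(all(h$lambda >= 0.3 & h$lambda <= 0.5))
  expect_equal(h$lr, vapply(h$epoch - 1, lr_schedule, 0,
                            base_lr = su$tc$base_lr))
})

test_that("early stopping restores the best-validation checkpoint", {
  su <- small_train_setup(seed = 5, epochs = 25)
  su$tc$patience <- 3L
  val <- su$ds$test
  fit <- train_model(mv_model(su$mc), su$ds$train, val_records = val,
                     config = su$tc)
  h <- fit$history
  expect_equal(fit$best_epoch, h$epoch[which.max(h$val_acc)])
  # the returned model scores the validation set exactly as the best epoch did
  p <- predict_proba(fit$model, val)
  acc <- mean((p >= 0.5) == (vapply(val, `[[`, 0L, "label") == 1))
  expect_equal(acc, max(h$val_acc))
  # stopping happened within patience epochs of the best
  expect_lte(nrow(h), fit$best_epoch + su$tc$patience)
})

test_that("disabling the contrastive term reduces training to cross-entropy", {
  su <- small_train_setup(seed = 6, epochs = 3, variant = "cba_bil")
  fit <- train_model(mv_model(su$mc), su$ds$train, config = su$tc)
  h <- fit$history
  expect_true(all(h$train_cont == 0))
  expect_equal(h$train_total, h$train_cls, tolerance = 1e-12)
})

test_that("training aborts with a diagnostic when the loss turns non-finite", {
  su <- small_train_setup(seed = 7, epochs = 4)
  m <- mv_model(su$mc)
  m$params$c_W[1] <- NaN  # corrupt weight: loss is non-finite immediately
  expect_error(train_model(m, su$ds$train, config = su$tc), "diverged")
})

test_that("two-stage mode pretrains contrastively before joint training", {
  su <- small_train_setup(seed = 8, epochs = 5)
  su$tc$schedule <- "two_stage"
  su$tc$pretrain_epochs <- 2L
  fit <- train_model(mv_model(su$mc), su$ds$train, config = su$tc)
  h <- fit$history
  expect_true(all(h$train_cls[1:2] == 0))       # no supervised signal yet
  expect_true(all(h$train_cls[3:5] > 0))
})

test_that("repeated runs are reproducible under the master seed", {
  su <- small_train_setup(seed = 9, n_pos = 24, epochs = 3)
  rr1 <- repeated_runs(su$ds$train, su$ds$test, su$mc, su$tc, n_runs = 2,
                       master_seed = 5)
  rr2 <- repeated_runs(su$ds$train, su$ds$test, su$mc, su$tc, n_runs = 2,
                       master_seed = 5)
  expect_identical(rr1$auroc, rr2$auroc)
  expect_length(rr1$auroc, 2)
  expect_true(all(rr1$auroc >= 0 & rr1$auroc <= 1))
})

test_that("the cross-modification matrix has consistent diagonal and shape", {
  suA <- small_train_setup(seed = 10, n_pos = 24, epochs = 3)
  dsB <- generate_dataset(
    synthetic_config(n_pos = 24, n_neg = 24, length = 15, motif = "GGAC",
                     motif_offset = -1, seed = 11),
    test_frac = 0.25)
  M <- cross_modification_matrix(list(a = suA$ds, b = list(train = dsB$train,
                                                           test = dsB$test)),
                                 suA$mc, suA$tc)
  expect_equal(dim(M), c(2, 2))
  expect_true(all(is.finite(M)))
  expect_equal(rownames(M), c("a", "b"))
  expect_error(cross_modification_matrix(list(a = suA$ds), suA$mc, suA$tc),
               "at least two")
})
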