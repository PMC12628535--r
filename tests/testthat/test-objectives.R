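test_that("cosine similarity matches hand values and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 2), c(1, 1)), 1)
  expect_equal(cosine_similarity(c(3, 4), c(4, 3)), 0.96)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("NT-Xent closed forms: N=1, identical projections, orthogonal negatives", {
  # N = 1: the denominator equals the numerator
  b1 <- contrastive_batch(matrix(c(1, 2, 1, 2), 2, 2), tau = 0.3)
  expect_equal(ntxent_pair_loss(b1, 1, 2), 0)
  expect_equal(ntxent_batch_loss(b1), 0)

  # all projections identical: loss = ln(2N - 1) for any tau and N
  for (N in c(1, 2, 4)) {
    for (tau in c(0.1, 0.5, 1)) {
      Z <- matrix(rep(c(0.3, -0.7, 0.2), each = 2 * N), 2 * N, 3)
      expect_equal(ntxent_batch_loss(contrastive_batch(Z, tau)),
                   log(2 * N - 1), tolerance = 1e-12)
    }
  }

  # N = 2, tau = 0.5, sim(pos) = 1, cross-pair sims 0
  Z <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 1, 0, 0))
  b <- contrastive_batch(Z, tau = 0.5)
  expect_equal(ntxent_pair_loss(b, 1, 2), log(1 + 2 * exp(-2)),
               tolerance = 1e-12)
  expect_equal(ntxent_batch_loss(b), log(1 + 2 * exp(-2)), tolerance = 1e-12)
})

test_that("batch loss is the mean of the 2N directed pair losses", {
  set.seed(8)
  Z <- matrix(rnorm(8 * 5), 8, 5)
  b <- contrastive_batch(Z, tau = 0.4)
  directed <- unlist(lapply(1:4, function(k) {
    c(ntxent_pair_loss(b, 2 * k - 1, 2 * k),
      ntxent_pair_loss(b, 2 * k, 2 * k - 1))
  }))
  expect_equal(ntxent_batch_loss(b), mean(directed), tolerance = 1e-12)
  # and the internal training-path value agrees with the exported ops
  expect_equal(methclr:::ntxent_loss_grad(Z, 0.4)$loss, mean(directed),
               tolerance = 1e-12)
})

test_that("NT-Xent decreases as positive-pair similarity rises, negatives fixed", {
  angles <- seq(pi / 2, 0.05, length.out = 8)
  losses <- vapply(angles, function(th) {
    Z <- rbind(c(1, 0, 0), c(cos(th), sin(th), 0),
               c(0, 0, 1), c(0, 0, 1))
    ntxent_pair_loss(contrastive_batch(Z, 0.5), 1, 2)
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("smaller temperature sharpens a correctly-ordered batch", {
  Z <- rbind(c(1, 0, 0), c(0.95, 0.1, 0), c(0, 1, 0), c(0.1, 0.9, 0.2))
  taus <- c(1, 0.5, 0.2, 0.1, 0.05)
  losses <- vapply(taus, function(tau) {
    ntxent_batch_loss(contrastive_batch(Z, tau))
  }, 0)
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("NT-Xent gradient matches finite differences", {
  set.seed(9)
  Z <- matrix(rnorm(6 * 4), 6, 4)
  g <- methclr:::ntxent_loss_grad(Z, 0.5)
  eps <- 1e-6
  for (ix in sample(length(Z), 8)) {
    Zp <- Z; Zp[ix] <- Zp[ix] + eps
    Zm <- Z; Zm[ix] <- Zm[ix] - eps
    num <- (methclr:::ntxent_loss_grad(Zp, 0.5)$loss -
              methclr:::ntxent_loss_grad(Zm, 0.5)$loss) / (2 * eps)
    expect_equal(g$dZ[ix], num, tolerance = 1e-5)
  }
})

test_that("cross-entropy matches hand values and clamps zero probabilities", {
  expect_equal(cross_entropy_loss(rbind(c(0, 1), c(1, 0)), c(1, 0)), 0)
  expect_equal(cross_entropy_loss(rbind(c(0.5, 0.5), c(0.5, 0.5)), c(1, 0)),
               log(2))
  expect_equal(cross_entropy_loss(matrix(c(0.2, 0.8), 1, 2), 1), -log(0.8))
  expect_true(is.finite(cross_entropy_loss(matrix(c(1, 0), 1, 2), 1)))
})

test_that("total loss is the lambda-weighted sum with enforced bounds", {
  expect_equal(total_loss(1.0, 2.0, 0.5), 2.0)
  expect_equal(total_loss(1.0, 0, 0.4), 1.0)
  expect_equal(total_loss(1.0, 2.0, 0.3), 1.6)
  expect_error(total_loss(1, 1, 0.2), "lambda")
  expect_error(total_loss(1, 1, 0.6), "lambda")
})

test_that("lambda is fixed for 10 epochs then tracks the validation trend", {
  st <- training_state()
  st$epoch <- 5
  st$val_acc_history <- seq(0.9, 0.5, length.out = 5)
  expect_equal(update_lambda(st)$lambda, 0.5)

  # decreasing accuracy after warm-up: lambda steps down to the 0.3 floor
  st$epoch <- 20
  lam <- numeric(0)
  for (i in 1:8) {
    st <- update_lambda(st)
    lam <- c(lam, st$lambda)
  }
  expect_equal(lam[1:4], c(0.45, 0.40, 0.35, 0.30))
  expect_true(all(lam >= 0.3))
  expect_equal(lam[8], 0.3)

  # increasing accuracy from the ceiling: lambda stays at 0.5
  st2 <- training_state()
  st2$epoch <- 20
  st2$val_acc_history <- seq(0.5, 0.9, length.out = 7)
  expect_equal(update_lambda(st2)$lambda, 0.5)
})

test_that("learning rate warms up over 5 epochs then decays by 0.9", {
  base <- 1e-3
  expect_equal(lr_schedule(0, base), base / 5)
  expect_equal(lr_schedule(4, base), base)
  expect_equal(lr_schedule(5, base), 0.9 * base)
  lrs <- vapply(5:30, lr_schedule, 0, base_lr = base)
  expect_true(all(diff(lrs) < 0))
  expect_equal(lr_schedule(10, base), base * 0.9^6)
})
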