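test_that("branch outputs and fused representation have the contracted dims", {
  m <- mv_model(model_config(seed = 1))  # default: 64 hidden units/direction
  be <- m$backend
  X <- embed_tokens(kmerize(rand_seq(41), 6), be)$X
  expect_equal(dim(X), c(38, 32))

  b1 <- branch1_forward(m, X)
  expect_length(b1$context, 128)      # 2 x 64, bidirectional
  expect_equal(dim(b1$seq), c(38, 128))
  expect_length(b1$weights, 38)
  expect_equal(sum(b1$weights), 1, tolerance = 1e-12)
  expect_true(all(b1$weights >= 0))

  xe <- cgr_trace(rand_seq(41))$states
  s2 <- branch2_forward(m, matrix(xe, 41, 1))
  expect_length(s2, 128)

  enc <- encode(m, list(X = X, X_extra = xe))
  expect_length(enc$h, 256)
  expect_equal(enc$h, c(enc$context, enc$branch2_summary))
  expect_equal(enc$context, b1$context)    # same eval-mode branch-1 pass
  expect_equal(enc$branch2_summary, s2)

  z <- project(m, enc$h)
  expect_length(z, 64)
  probs <- classify(m, enc$h)
  expect_length(probs, 2)
  expect_equal(sum(probs), 1, tolerance = 1e-6)
})

test_that("eval-mode forward passes are deterministic", {
  m <- mv_model(tiny_model_config())
  X <- embed_tokens(kmerize(rand_seq(12), 3), m$backend)$X
  xe <- cgr_trace(rand_seq(12))$states
  e1 <- encode(m, list(X = X, X_extra = xe))
  e2 <- encode(m, list(X = X, X_extra = xe))
  expect_identical(e1$h, e2$h)
  expect_identical(classify(m, e1$h), classify(m, e2$h))
  expect_identical(project(m, e1$h), project(m, e2$h))
})

test_that("attention pooling handles the degenerate and hand-derived cases", {
  # single timestep
  one <- attention_pool(matrix(c(2, 5), 1, 2), matrix(0, 2, 2), c(0, 0),
                        c(0, 0))
  expect_equal(one$weights, 1)
  expect_equal(one$context, c(2, 5))

  # two identical timesteps: symmetry forces 0.5/0.5
  H <- rbind(c(1, 2), c(1, 2))
  two <- attention_pool(H, matrix(rnorm(4), 2, 2), rnorm(2), rnorm(2))
  expect_equal(two$weights, c(0.5, 0.5))

  # scores e = (ln 3, 0) -> weights (0.75, 0.25), context (0.75, 0.25)
  H <- rbind(c(1, 0), c(0, 1))
  Wa <- rbind(c(1, 0), c(0, 0))
  v <- c(log(3) / tanh(1), 0)
  got <- attention_pool(H, Wa, c(0, 0), v)
  expect_equal(got$weights, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(got$context, c(0.75, 0.25), tolerance = 1e-12)

  expect_error(attention_pool(matrix(0, 0, 2), matrix(0, 2, 2), 0, 0),
               "non-empty")
})

test_that("zero attention parameters give the unweighted mean context", {
  m <- mv_model(tiny_model_config())
  m$params$a_Wa[] <- 0
  m$params$a_ba[] <- 0
  m$params$a_v[] <- 0
  X <- embed_tokens(kmerize(rand_seq(12), 3), m$backend)$X
  b1 <- branch1_forward(m, X)
  expect_equal(b1$weights, rep(1 / 12, 12), tolerance = 1e-12)
  expect_equal(b1$context, colMeans(b1$seq), tolerance = 1e-10)
})

test_that("zero final-layer classifier weights yield uniform probabilities", {
  m <- constant_output_model()
  expect_equal(classify(m, rnorm(m$config$h_dim)), c(0.5, 0.5))
})

test_that("ablation flags reshape the fused representation", {
  X <- NULL
  xe <- cgr_trace(rand_seq(12))$states
  mk <- function(...) mv_model(tiny_model_config(...))

  m_b1 <- mk(use_branch2 = FALSE)
  Xe <- embed_tokens(kmerize(rand_seq(12), 3), m_b1$backend)$X
  expect_length(encode(m_b1, list(X = Xe))$h, 6)          # context only

  m_b2 <- mk(use_branch1 = FALSE)
  expect_length(encode(m_b2, list(X_extra = xe))$h, 6)    # summary only

  m_cnn <- mk(branch1_arch = "cnn", use_branch2 = FALSE)
  expect_length(encode(m_cnn, list(X = embed_tokens(kmerize(rand_seq(12), 3),
                                                    m_cnn$backend)$X))$h,
                6)                                        # conv_filters
  m_cb <- mk(branch1_arch = "cnn_bilstm", use_branch2 = FALSE)
  enc <- encode(m_cb, list(X = embed_tokens(kmerize(rand_seq(12), 3),
                                            m_cb$backend)$X))
  expect_length(enc$h, 6)
  expect_null(enc$attn_weights)                           # no attention head
  expect_error(mk(use_branch1 = FALSE, use_branch2 = FALSE), "at least one")
})

test_that("an oversized projection dimension triggers the compression warning", {
  expect_warning(model_config(proj_dim = 300), "compress")
})

test_that("projection similarity cost drops from O(B^2 D) to O(B^2 P) + O(B D P)", {
  B <- 512; D <- 256; P <- 64
  cost_h <- B^2 * D                 # pairwise similarity on h
  cost_z <- B^2 * P + B * D * P     # project, then similarity on z
  expect_lt(cost_z, cost_h * 0.75)
  # multiply-count of the actual computation agrees with the formulas
  expect_equal(length(matrix(0, B, D) %*% matrix(0, D, P)) * D, B * P * D)
})

test_that("analytic gradients of the full multi-task loss match finite differences", {
  cfg <- tiny_model_config(dropout_conv = 0, dropout_lstm = 0,
                           dropout_head = 0)
  model <- mv_model(cfg)
  recs <- tiny_records(3)
  feats <- methclr:::prepare_features(recs, model$config)
  lambda <- 0.5

  loss_fn <- function(model) {
    B <- length(feats$y)
    Xf <- methclr:::embed_ids_flat(feats$ids, model$backend$E)
    enc <- methclr:::encoder_fwd_batch(model, Xf, feats$Xe, B, train = TRUE)
    clf <- methclr:::classifier_fwd(model, enc$h, train = TRUE)
    ce <- cross_entropy_loss(clf$probs, feats$y)
    e2 <- methclr:::encoder_fwd_batch(model, Xf, feats$Xe, B, train = TRUE)
    e3 <- methclr:::encoder_fwd_batch(model, Xf, feats$Xe, B, train = TRUE)
    zq <- methclr:::projection_fwd(model, e2$h, TRUE)$z
    zk <- methclr:::projection_fwd(model, e3$h, TRUE)$z
    Z <- methclr:::interleave_rows(zq, zk)
    ce + lambda * methclr:::ntxent_loss_grad(Z, model$config$tau)$loss
  }

  cfgT <- train_config(augment = augmentation_config(p_mask = 0, eta = 0))
  st <- methclr:::train_step(model, feats$ids, feats$Xe, feats$y, lambda, cfgT)

  eps <- 1e-6
  set.seed(21)
  for (nm in names(st$grads)) {
    g <- st$grads[[nm]]
    for (ix in sample(length(g), min(3, length(g)))) {
      m2 <- model
      if (nm == "E") {
        m2$backend$E[ix] <- m2$backend$E[ix] + eps
        lp <- loss_fn(m2)
        m2$backend$E[ix] <- m2$backend$E[ix] - 2 * eps
        lm <- loss_fn(m2)
      } else {
        m2$params[[nm]][ix] <- m2$params[[nm]][ix] + eps
        lp <- loss_fn(m2)
        m2$params[[nm]][ix] <- m2$params[[nm]][ix] - 2 * eps
        lm <- loss_fn(m2)
      }
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[ix], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, ix))
    }
  }
})

test_that("model checkpoints round-trip through the archive + sidecar", {
  m <- mv_model(tiny_model_config())
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$config$k, m$config$k)
  expect_error(load_model("/no/such/model.rds"), "not found")
})
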