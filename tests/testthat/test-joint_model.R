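# Loss-formula oracles, architecture contracts and training sanity for the
# joint Siamese CNN.

test_that("classification loss matches the hand-coded binary cross-entropy", {
  bce_oracle <- function(y, p) -sum(y * log(p) + (1 - y) * log(1 - p))
  expect_lt(classification_loss(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-6)
  expect_equal(classification_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(classification_loss(c(1, 1), c(0.9, 0.8)),
               -(log(0.9) + log(0.8)), tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    y <- sample(0:1, 14, replace = TRUE)
    p <- runif(14, 0.01, 0.99)
    expect_equal(classification_loss(y, p), bce_oracle(y, p), tolerance = 1e-9)
  }
  # clamping keeps the loss finite at exact 0/1 probabilities
  expect_true(is.finite(classification_loss(c(1, 0), c(0, 1))))
})

test_that("contrastive loss matches its closed form, including both zeros", {
  expect_equal(contrastive_loss(1, 0, 1), 0)
  expect_equal(contrastive_loss(0, 1, 1), 0)     # dissimilar at the margin
  expect_equal(contrastive_loss(0, 0, 1), 0.5)   # (1/2) margin^2
  oracle <- function(Y, e, m) Y * e^2 / 2 + (1 - Y) * max(0, m - e)^2 / 2
  set.seed(3)
  for (i in 1:30) {
    Y <- sample(0:1, 1); e <- runif(1, 0, 3); m <- runif(1, 0.5, 2)
    expect_equal(contrastive_loss(Y, e, m), oracle(Y, e, m), tolerance = 1e-9)
  }
  expect_error(contrastive_loss(1, -0.1), ">= 0")
})

test_that("contrastive-loss gradient in e passes a finite-difference check", {
  m <- 1.3
  dL_de <- function(Y, e) if (Y == 1) e else -max(0, m - e)
  for (e0 in c(0.2, m, 2 * m)) {
    for (Y in 0:1) {
      h <- 1e-6
      num <- (contrastive_loss(Y, e0 + h, m) - contrastive_loss(Y, e0 - h, m)) / (2 * h)
      expect_equal(num, dL_de(Y, e0), tolerance = 1e-4)
    }
  }
})

test_that("joint loss sums weighted components and rejects non-finite input", {
  expect_equal(joint_loss(0, 0, 0), 0)
  expect_equal(joint_loss(0.3, 0.2, 0.5), 1.0)
  expect_equal(joint_loss(0.3, 0.2, 0.5, weights = c(1, 1, 0)), 0.5)
  expect_equal(joint_loss(0.3, 0.2, 0.5, weights = c(0, 0, 1)), 0.5)
  expect_error(joint_loss(NaN, 0, 0), "cls_a")
  expect_error(joint_loss(0, 0, Inf), "sim")
})

test_that("valid convolution over the visit axis has length v - h + 1", {
  set.seed(4)
  X <- matrix(rnorm(200 * 8), 200, 8)
  W <- patsim:::glorot(3 * 8, 4, c(3 * 8, 4))
  attr(W, "kernel_width") <- 3L
  out <- patsim:::conv1d_forward(X, W, numeric(4))
  expect_equal(nrow(out$out), 198)
  # all-zero input with zero bias gives all-zero features
  z <- patsim:::conv1d_forward(matrix(0, 20, 8), W, numeric(4))
  expect_true(all(z$out == 0))
  # indicator filter: feature = positive part of one channel's window sum
  W1 <- matrix(0, 2 * 2, 1)
  attr(W1, "kernel_width") <- 2L
  W1[c(1, 3), 1] <- 1  # channel 1 at both window offsets
  toy <- matrix(c(1, -2, 3, 4, -1,   10, 20, 30, 40, 50), 5, 2)
  f <- patsim:::conv1d_forward(toy, W1, 0)$out
  expect_equal(as.vector(f), pmax(c(1 - 2, -2 + 3, 3 + 4, 4 - 1), 0))
})

test_that("self-attention weights are a row-stochastic matrix and shapes are kept", {
  set.seed(5)
  X <- matrix(rnorm(12 * 6), 12, 6)
  at <- patsim:::attention_forward(X)
  expect_equal(dim(at$out), dim(X))
  expect_equal(rowSums(at$cache$A), rep(1, 12), tolerance = 1e-6)
  expect_true(all(at$cache$A >= 0))
  expect_true(all(is.finite(at$out)))
  # constant-in-time input stays finite and keeps its shape
  Xc <- matrix(rep(rnorm(6), each = 12), 12, 6)
  expect_equal(dim(patsim:::attention_forward(Xc)$out), dim(Xc))
})

test_that("encoder emits output_dim for any valid input and ignores padding", {
  cfg <- encoder_config(v_max = 40, embed_dim = 8, block_filters = c(6, 4, 3),
                        output_dim = 17, dropout_rate = 0)
  set.seed(6)
  params <- patsim:::init_joint_params(cfg)
  for (v in c(1, 20, 40)) {
    X <- matrix(0, 40, 8)
    X[seq_len(v), ] <- rnorm(v * 8)
    z <- patsim:::encoder_forward(params, cfg, X)$z
    expect_length(z, 17)
    expect_true(all(is.finite(z)))
  }
  # inference determinism
  X <- matrix(rnorm(40 * 8), 40, 8)
  z1 <- patsim:::encoder_forward(params, cfg, X)$z
  z2 <- patsim:::encoder_forward(params, cfg, X)$z
  expect_identical(z1, z2)
  # attention off acts as identity at the attention stage
  cfg_noatt <- encoder_config(v_max = 40, embed_dim = 8, block_filters = c(6, 4, 3),
                              output_dim = 17, dropout_rate = 0, attention = FALSE)
  z3 <- patsim:::encoder_forward(params, cfg_noatt, X)$z
  expect_false(identical(z1, z3))
  expect_length(z3, 17)
})

test_that("analytic gradients of the full joint objective match finite differences", {
  # Central finite differences are only a valid oracle away from the BCE
  # clamp: the analytic gradient uses the standard unclamped (p - y), so the
  # check runs in a non-saturated regime (scaled-down parameters and inputs)
  # and asserts the head probabilities stay well inside (0, 1).
  cfg <- encoder_config(v_max = 30, embed_dim = 16, block_filters = c(4, 3, 2),
                        output_dim = 8, dropout_rate = 0)
  set.seed(5)
  params <- patsim:::params_map(patsim:::init_joint_params(cfg),
                                function(x) 0.4 * x)
  Xa <- matrix(rnorm(30 * 16, sd = 0.5), 30, 16)
  Xb <- matrix(rnorm(30 * 16, sd = 0.5), 30, 16)
  ya <- sample(0:1, 14, replace = TRUE)
  yb <- sample(0:1, 14, replace = TRUE)
  pa <- patsim:::head_forward(params, patsim:::encoder_forward(params, cfg, Xa)$z)
  expect_true(all(pa > 1e-3 & pa < 1 - 1e-3))
  h <- 1e-6
  for (Y in 0:1) {
    for (norm_flag in c(TRUE, FALSE)) {
      res <- patsim:::joint_pair_grad(params, cfg, Xa, Xb, ya, yb, Y, 1,
                                      c(1, 1, 1), training = FALSE,
                                      normalize = norm_flag)
      fl <- patsim:::params_flatten(params)
      gl <- patsim:::params_flatten(res$grads)
      idx <- sample(length(fl), 20)
      for (i in idx) {
        p1 <- fl; p1[i] <- p1[i] + h
        p2 <- fl; p2[i] <- p2[i] - h
        l1 <- patsim:::joint_pair_loss(patsim:::params_unflatten(params, p1), cfg,
                                       Xa, Xb, ya, yb, Y, 1, c(1, 1, 1),
                                       normalize = norm_flag)
        l2 <- patsim:::joint_pair_loss(patsim:::params_unflatten(params, p2), cfg,
                                       Xa, Xb, ya, yb, Y, 1, c(1, 1, 1),
                                       normalize = norm_flag)
        fd <- (l1 - l2) / (2 * h)
        expect_lt(abs(gl[i] - fd) / max(abs(fd) + abs(gl[i]), 1e-3), 1e-4)
      }
    }
  }
})

test_that("the padded-matrix contract makes encodings depend only on real visits", {
  ch <- tiny_cohort(n = 4, seed = 21)
  docs <- unlist(lapply(ch, build_visit_documents), recursive = FALSE)
  emb <- train_embedder(docs, dim = 8, backend = "hash")
  pm1 <- build_patient_matrix(ch[[1]], emb, v_max = 30)
  pm2 <- build_patient_matrix(ch[[1]], emb, v_max = 30)
  cfg <- encoder_config(v_max = 30, embed_dim = 8, block_filters = c(4, 3, 2),
                        output_dim = 10, dropout_rate = 0)
  set.seed(8)
  params <- patsim:::init_joint_params(cfg)
  expect_identical(patsim:::encoder_forward(params, cfg, pm1$matrix)$z,
                   patsim:::encoder_forward(params, cfg, pm2$matrix)$z)
  # padding rows are exactly zero by construction
  if (pm1$n_visits < 30) {
    expect_equal(sum(abs(pm1$matrix[(pm1$n_visits + 1):30, ])), 0)
  }
})

test_that("a few epochs of joint training reduce the total loss on a fixture", {
  ch <- tiny_cohort(n = 30, seed = 31)
  mats <- tiny_matrices(ch)
  pr <- build_pair_dataset(ch, n_pairs = 120, seed = 5)
  cfg <- encoder_config(v_max = 30, embed_dim = 16, block_filters = c(8, 6, 4),
                        output_dim = 16)
  tc <- train_config(batch_size = 32, max_epochs = 3, patience = 5,
                     val_fraction = 0, seed = 9)
  model <- train_joint(pr, mats, cfg, tc)
  expect_s3_class(model, "joint_model")
  expect_lte(model$history$train_total[3], model$history$train_total[1])
  # encode/pair surface
  z <- encode_patient(model, mats[[1]])
  expect_length(z, 16)
  expect_equal(pair_distance(model, mats[[1]], mats[[1]]), 0)
  probs <- predict_feature_probs(model, mats[[1]])
  expect_true(all(probs > 0 & probs < 1))
  # ablation configs train under the same surface
  tc_sim <- train_config(batch_size = 32, max_epochs = 2, patience = 5,
                         val_fraction = 0, seed = 9, loss_weights = c(0, 0, 1))
  m_sim <- train_joint(pr, mats, cfg, tc_sim)
  expect_equal(m_sim$history$train_cls[1], 0)
  tc_feat <- train_config(batch_size = 32, max_epochs = 2, patience = 5,
                          val_fraction = 0, seed = 9, loss_weights = c(1, 1, 0))
  m_feat <- train_joint(pr, mats, cfg, tc_feat)
  expect_equal(m_feat$history$train_sim[1], 0)
})

test_that("similarity scores are bounded, symmetric and anchored at the margin", {
  expect_equal(similarity_score(0, 1), 1)
  expect_equal(similarity_score(1, 1), 0)
  expect_equal(similarity_score(2.5, 1), 0)   # clamp beyond the margin
  expect_equal(similarity_score(0.25, 1), 0.75)
  expect_error(similarity_score(-1, 1), ">= 0")
  ch <- tiny_cohort(n = 6, seed = 41)
  mats <- tiny_matrices(ch)
  pr <- build_pair_dataset(ch, n_pairs = 10, seed = 5)
  cfg <- encoder_config(v_max = 30, embed_dim = 16, block_filters = c(4, 3, 2),
                        output_dim = 8)
  tc <- train_config(batch_size = 8, max_epochs = 1, patience = 2,
                     val_fraction = 0, seed = 3)
  model <- train_joint(pr, mats, cfg, tc)
  d_ab <- pair_distance(model, mats[[1]], mats[[2]])
  d_ba <- pair_distance(model, mats[[2]], mats[[1]])
  expect_equal(d_ab, d_ba, tolerance = 1e-12)
})
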