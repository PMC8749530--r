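test_that("patient vectors average only the real visit rows", {
  ch <- tiny_cohort(n = 4, seed = 17)
  mats <- tiny_matrices(ch)
  pm <- mats[[1]]
  v <- pm$n_visits
  expect_equal(patient_vector(pm),
               colMeans(pm$matrix[seq_len(v), , drop = FALSE]))
  # one visit: the vector is that row
  one <- pm; one$n_visits <- 1L
  expect_equal(patient_vector(one), pm$matrix[1, ])
  # junk in padding rows never contributes
  junk <- pm
  if (v < nrow(junk$matrix)) {
    junk$matrix[(v + 1):nrow(junk$matrix), ] <- 99
    expect_equal(patient_vector(junk), patient_vector(pm))
  }
  bad <- pm; bad$n_visits <- 0L
  expect_error(patient_vector(bad), "no real visits")
})

test_that("euclidean and cosine behave like their definitions", {
  eu <- fit_metric("euclidean")
  co <- fit_metric("cosine")
  u <- c(1, 2, 3); v <- c(1, 2, 3)
  expect_equal(metric_distance(eu, u, v), 0)
  expect_equal(metric_distance(co, u, v), 1)
  expect_equal(metric_distance(eu, c(0, 0), c(3, 4)), 5)
  expect_error(metric_distance(co, c(0, 0), c(1, 1)), "zero vector")
})

test_that("mahalanobis with identity M reduces to euclidean", {
  m <- structure(list(kind = "mahalanobis", M = diag(6), threshold = NA_real_),
                 class = "metric_model")
  eu <- fit_metric("euclidean")
  set.seed(5)
  for (i in 1:25) {
    u <- rnorm(6); v <- rnorm(6)
    expect_equal(metric_distance(m, u, v), metric_distance(eu, u, v),
                 tolerance = 1e-9)
  }
})

test_that("the 2-d mahalanobis toy matches the hand computation", {
  # M = inverse of diag(4, 1); u - v = (2, 1) -> sqrt(2^2/4 + 1^2/1) = sqrt(2)
  m <- structure(list(kind = "mahalanobis", M = solve(diag(c(4, 1))),
                      threshold = NA_real_), class = "metric_model")
  expect_equal(metric_distance(m, c(2, 1), c(0, 0)), sqrt(2), tolerance = 1e-12)
})

test_that("fitted mahalanobis and lsml matrices are symmetric PSD", {
  set.seed(6)
  n <- 60
  X <- cbind(rnorm(n), rnorm(n), rnorm(n, sd = 2))
  rownames(X) <- sprintf("P%03d", seq_len(n))
  cls <- rep(0:1, each = n / 2)
  X[cls == 1, 1] <- X[cls == 1, 1] + 4
  pairs <- expand.grid(i = 1:n, j = 1:n)
  pairs <- pairs[pairs$i < pairs$j, ][sample(choose(n, 2), 400), ]
  pairs <- data.frame(id_a = rownames(X)[pairs$i], id_b = rownames(X)[pairs$j],
                      sim_label = as.integer(cls[pairs$i] == cls[pairs$j]))
  for (kind in c("mahalanobis", "lsml")) {
    mm <- suppressWarnings(fit_metric(kind, vectors = X, pairs = pairs))
    expect_equal(mm$M, t(mm$M), tolerance = 1e-9)
    ev <- eigen(mm$M, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("lsml shrinks within-class distances relative to between-class", {
  set.seed(7)
  n <- 40
  # two clusters separated along x, label = same cluster
  X <- cbind(c(rnorm(n / 2), rnorm(n / 2) + 6), rnorm(n, sd = 3))
  rownames(X) <- sprintf("P%03d", seq_len(n))
  cls <- rep(0:1, each = n / 2)
  grid <- expand.grid(i = 1:n, j = 1:n)
  grid <- grid[grid$i < grid$j, ]
  pairs <- data.frame(id_a = rownames(X)[grid$i], id_b = rownames(X)[grid$j],
                      sim_label = as.integer(cls[grid$i] == cls[grid$j]))
  fit <- lsml_fit(X, pairs, k_local = 5)
  ratio_for <- function(M) {
    md <- function(i, j) {
      d <- X[i, ] - X[j, ]; sqrt(drop(crossprod(d, M %*% d)))
    }
    w <- mean(mapply(md, grid$i[pairs$sim_label == 1], grid$j[pairs$sim_label == 1]))
    b <- mean(mapply(md, grid$i[pairs$sim_label == 0], grid$j[pairs$sim_label == 0]))
    w / b
  }
  expect_lt(ratio_for(fit$M), ratio_for(diag(2)))
})

test_that("degenerate lsml with no separating structure falls back to identity", {
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  rownames(X) <- sprintf("P%02d", 1:10)
  # labels independent of geometry and symmetric: scatter matrices coincide
  pairs <- data.frame(id_a = rownames(X)[c(1, 2)], id_b = rownames(X)[c(3, 4)],
                      sim_label = c(1, 0))
  fit <- suppressWarnings(lsml_fit(X, pairs, k_local = 2))
  expect_true(all(is.finite(fit$M)))
  expect_equal(fit$M, t(fit$M), tolerance = 1e-9)
})

test_that("threshold selection recovers a perfect separator and edge cases", {
  scores <- c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3)
  labels <- c(1, 1, 1, 0, 0, 0)
  th <- choose_threshold(scores, labels, direction = "less")
  expect_equal(th$f1, 1)
  expect_true(th$threshold > 0.3 && th$threshold < 1.1)
  # tau beyond all distances predicts everything similar; tau below none
  m <- fit_metric("euclidean"); m$threshold <- Inf
  X <- matrix(rnorm(12), 6, 2, dimnames = list(sprintf("P%d", 1:6), NULL))
  pr <- data.frame(id_a = c("P1", "P2"), id_b = c("P3", "P4"))
  expect_equal(classify_pairs(m, X, pr), c(1L, 1L))
  m$threshold <- 0
  expect_equal(classify_pairs(m, X, pr), c(0L, 0L))
})

test_that("run_baseline fits, thresholds on train, and reports on test", {
  ch <- tiny_cohort(n = 25, seed = 19)
  mats <- tiny_matrices(ch)
  pr <- build_pair_dataset(ch, n_pairs = 120, seed = 3)
  vecs <- t(vapply(mats, patient_vector, numeric(16)))
  rownames(vecs) <- names(mats)
  for (kind in c("euclidean", "cosine", "mahalanobis")) {
    out <- run_baseline(kind, vecs, pr)
    expect_true(out$report$f1 >= 0 && out$report$f1 <= 1)
    expect_false(is.na(out$model$threshold))
  }
})
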