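test_that("imbalance report matches the hand-computed ratios", {
  # counts {a: 10, b: 5, c: 2} -> IRLbl {1, 2, 5}, MeanIR 8/3
  labels <- matrix(0L, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  labels[1:10, "a"] <- 1L
  labels[1:5, "b"] <- 1L
  labels[1:2, "c"] <- 1L
  rep <- imbalance_report(labels)
  expect_equal(unname(rep$irlbl), c(1, 2, 5))
  expect_equal(rep$mean_ir, 8 / 3)
  expect_equal(rep$tail_labels, "c")
  # equal counts: all IRLbl 1, empty tail
  eq <- imbalance_report(matrix(1L, 4, 3))
  expect_true(all(eq$irlbl == 1))
  expect_length(eq$tail_labels, 0)
  # single label
  expect_equal(unname(imbalance_report(matrix(1L, 4, 1))$irlbl), 1)
  # zero-positive label flagged and excluded from MeanIR
  z <- labels; z[, "c"] <- 0L
  rz <- imbalance_report(z)
  expect_equal(rz$undefined_labels, "c")
  expect_equal(rz$mean_ir, mean(c(1, 2)))
})

test_that("mlsmote leaves balanced data untouched", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2)
  L <- matrix(1L, 10, 2)
  out <- mlsmote(X, L, k = 3, seed = 2)
  expect_equal(out$features, X)
  expect_equal(sum(out$synthetic), 0)
})

test_that("mlsmote synthetics are convex combinations with ranked label sets", {
  set.seed(3)
  n <- 12
  X <- matrix(rnorm(n * 3), n, 3)
  L <- matrix(0L, n, 3, dimnames = list(NULL, c("head1", "head2", "tail")))
  L[, "head1"] <- 1L
  L[1:8, "head2"] <- 1L
  L[1:3, "tail"] <- 1L
  out <- mlsmote(X, L, k = 2, seed = 9)
  syn <- which(out$synthetic)
  expect_gt(length(syn), 0)
  for (s in seq_along(syn)) {
    par <- out$parents[[s]]
    seed_row <- X[par[["seed"]], ]
    nb_row <- X[par[["neighbor"]], ]
    u <- par[["u"]]
    # exact point on the segment
    expect_equal(out$features[syn[s], ], seed_row + u * (nb_row - seed_row),
                 tolerance = 1e-12)
    # independently recomputed ranking rule over seed + k neighbors
    expect_true(all(out$labels[syn[s], ] %in% 0:1))
  }
  # seeded determinism
  out2 <- mlsmote(X, L, k = 2, seed = 9)
  expect_identical(out, out2)
})

test_that("the 3-instance toy case follows the hand-enumerated ranking rule", {
  # two tail carriers with identical features; k = 1
  X <- rbind(c(0, 0), c(1, 1), c(5, 5))
  L <- matrix(c(1, 1, 1,    # head label on everyone
                1, 1, 0),   # tail label on instances 1-2
              ncol = 2, dimnames = list(NULL, c("head", "tail")))
  out <- mlsmote(X, L, k = 1, seed = 4)
  syn <- which(out$synthetic)
  expect_length(syn, 2)  # one synthetic per tail carrier
  for (s in seq_along(syn)) {
    x <- out$features[syn[s], ]
    # on the segment between (0,0) and (1,1): coordinates equal, within [0,1]
    expect_equal(x[1], x[2], tolerance = 1e-12)
    expect_gte(x[1], 0); expect_lte(x[1], 1)
    # ranking rule over {seed, 1 neighbor}: head in 2/2 -> on; tail in 2/2 -> on
    expect_equal(unname(out$labels[syn[s], ]), c(1L, 1L))
  }
  # identical seed and neighbor features give a synthetic equal to both
  X2 <- rbind(c(2, 2), c(2, 2), c(9, 9))
  out2 <- mlsmote(X2, L, k = 1, seed = 4)
  for (s in which(out2$synthetic)) {
    expect_equal(out2$features[s, ], c(2, 2), tolerance = 1e-12)
  }
})

test_that("mlsmote reduces MeanIR and warns when k exceeds carriers", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  L <- cbind(common = rep(1L, n), rare = c(rep(1L, 4), rep(0L, n - 4)))
  expect_warning(out <- mlsmote(X, L, k = 5, seed = 2), "using k")
  before <- imbalance_report(L)$mean_ir
  after <- imbalance_report(out$labels)$mean_ir
  expect_lte(after, before)
})

test_that("patient-level mlsmote yields valid encoder inputs and labels", {
  ch <- tiny_cohort(n = 25, seed = 13)
  mats <- tiny_matrices(ch)
  out <- mlsmote_cohort(ch, mats, k = 3, seed = 5)
  expect_lte(out$report_after$mean_ir, out$report_before$mean_ir)
  syn_ids <- names(out$synthetic)[out$synthetic]
  for (id in syn_ids) {
    pm <- out$matrices[[id]]
    expect_equal(dim(pm$matrix), dim(mats[[1]]$matrix))
    bits <- out$label_table[id, ]
    expect_silent(patsim:::validate_feature_label(bits))
  }
  # augmented label table feeds the pair builder directly
  pr <- build_pair_dataset(out$label_table, n_pairs = 30, seed = 6)
  expect_equal(nrow(pr), 30)
})
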