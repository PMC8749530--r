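test_that("age, blood-pressure and BMI binning follow the group boundaries", {
  expect_equal(bin_age(c(0, 30, 31, 45, 60, 61, 90)), c(1, 1, 2, 2, 2, 3, 3))
  expect_error(bin_age(-1), ">= 0")
  expect_equal(bin_bp(125, 82), 1)   # prehypertension
  expect_equal(bin_bp(110, 70), 1)   # below the prehypertension floor
  expect_equal(bin_bp(145, 95), 2)   # stage 1 on both readings
  expect_equal(bin_bp(165, 85), 3)   # stage 2 by SBP alone
  expect_equal(bin_bp(150, 105), 3)  # DBP forces stage 2
  expect_error(bin_bp(80, 90), "sbp > dbp")
  expect_equal(bin_bmi(c(18.4, 18.5, 20.0, 22.9, 23.0, 30)), c(1, 2, 2, 2, 3, 3))
  expect_error(bin_bmi(0), "> 0")
})

test_that("binning is total: every valid reading maps to exactly one group", {
  set.seed(42)
  for (i in 1:200) {
    age <- sample(0:110, 1)
    dbp <- runif(1, 40, 130)
    sbp <- dbp + runif(1, 1, 80)
    bmi <- runif(1, 10.1, 59.9)
    expect_true(bin_age(age) %in% 1:3)
    expect_true(bin_bp(sbp, dbp) %in% 1:3)
    expect_true(bin_bmi(bmi) %in% 1:3)
  }
})

test_that("the worked patient pair reproduces its printed feature bits and label", {
  recs <- worked_example_records()
  la <- feature_label(recs$a)
  lb <- feature_label(recs$b)
  expect_equal(as.integer(la), c(0, 1, 0, 1, 0, 0, 1, 0, 0, 0, 1, 1, 1, 0))
  expect_equal(as.integer(lb), c(0, 1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 0, 1, 0))
  expect_equal(count_matches(la, lb), 4)
  expect_equal(similarity_label(la, lb), 1)
})

test_that("match counting is symmetric, reflexive and agrees with brute force", {
  set.seed(9)
  for (i in 1:50) {
    a <- random_feature_bits()
    b <- random_feature_bits()
    expect_equal(count_matches(a, b), count_matches(b, a))
    expect_equal(count_matches(a, b), oracle_match_count(a, b))
    expect_equal(similarity_label(a, b), as.integer(oracle_match_count(a, b) >= 4))
  }
  # reflexivity: a patient always shares its own four one-hot groups plus its
  # diseases, so a self-pair is always labeled similar
  a <- random_feature_bits()
  expect_equal(count_matches(a, a), 4 + sum(a[12:14]))
  expect_gte(count_matches(a, a), 4)
  expect_equal(similarity_label(a, a), 1)
})

test_that("similarity rule matches direct category comparison over all valid patterns", {
  # enumerate every valid bit pattern (3*2*3*3*8 = 432) against a fixed reference
  ref <- c(0, 1, 0, 1, 0, 0, 1, 0, 0, 0, 1, 1, 1, 0)
  patterns <- expand.grid(age = 1:3, sex = 1:2, bp = 1:3, bmi = 1:3,
                          d1 = 0:1, d2 = 0:1, d3 = 0:1)
  for (r in seq_len(nrow(patterns))) {
    bits <- integer(14)
    bits[patterns$age[r]] <- 1L
    bits[3 + patterns$sex[r]] <- 1L
    bits[5 + patterns$bp[r]] <- 1L
    bits[8 + patterns$bmi[r]] <- 1L
    bits[12:14] <- unlist(patterns[r, c("d1", "d2", "d3")])
    expect_equal(similarity_label(ref, bits),
                 as.integer(oracle_match_count(ref, bits) >= 4))
  }
})

test_that("labels with multiple bits in a one-hot span are rejected", {
  bad <- random_feature_bits()
  bad[1:3] <- c(1L, 1L, 0L)
  expect_error(count_matches(bad, random_feature_bits()), "age")
})

test_that("pair datasets are canonical, duplicate-free and split as requested", {
  ch <- tiny_cohort(n = 12, seed = 2)
  pr <- build_pair_dataset(ch, n_pairs = 10, split_ratio = 0.8, seed = 4)
  expect_equal(nrow(pr), 10)
  expect_equal(sum(pr$split == "train"), 8)
  expect_equal(sum(pr$split == "test"), 2)
  expect_true(all(pr$id_a < pr$id_b))           # canonical order, no self-pairs
  expect_equal(anyDuplicated(paste(pr$id_a, pr$id_b)), 0)
  expect_equal(pr$sim_label, as.integer(pr$match_count >= 4))
  # seeded determinism
  pr2 <- build_pair_dataset(ch, n_pairs = 10, split_ratio = 0.8, seed = 4)
  expect_identical(pr, pr2)
  # cohort of 2 has exactly one pair; asking for more errors
  ch2 <- ch[1:2]; class(ch2) <- "patient_cohort"
  expect_equal(nrow(build_pair_dataset(ch2, n_pairs = 1, seed = 1)), 1)
  expect_error(build_pair_dataset(ch2, n_pairs = 2, seed = 1), "exceeds")
})

test_that("patient-disjoint splitting keeps train and test patients apart", {
  ch <- tiny_cohort(n = 30, seed = 6)
  pr <- build_pair_dataset(ch, n_pairs = 40, split_ratio = 0.8, seed = 4,
                           patient_disjoint = TRUE)
  tr_ids <- unique(c(pr$id_a[pr$split == "train"], pr$id_b[pr$split == "train"]))
  te_ids <- unique(c(pr$id_a[pr$split == "test"], pr$id_b[pr$split == "test"]))
  expect_length(intersect(tr_ids, te_ids), 0)
})

test_that("pair CSV round-trips", {
  ch <- tiny_cohort(n = 8, seed = 2)
  pr <- build_pair_dataset(ch, n_pairs = 6, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pairs_csv(pr, f)
  back <- read_pairs_csv(f)
  expect_equal(back, pr)
})
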