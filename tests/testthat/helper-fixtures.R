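# Shared fixtures, built in code at test time.

# A tiny deterministic cohort + hash-embedded matrices for unit tests.
tiny_cohort <- function(n = 20, seed = 7, v_max = 30) {
  generate_cohort(cohort_config(n_patients = n, visit_nb_mu = 6,
                                max_visits = v_max, seed = seed))
}

tiny_matrices <- function(cohort, dim = 16, v_max = 30) {
  docs <- unlist(lapply(cohort, build_visit_documents), recursive = FALSE)
  emb <- train_embedder(docs, dim = dim, backend = "hash")
  build_cohort_matrices(cohort, emb, v_max = v_max)
}

# Hand-built records for the worked similarity-labeling example: both male,
# 45 years, overweight BMI; A has stage-1 BP and diabetes + cerebrovascular
# disease, B stage-2 BP and cerebrovascular disease only.
worked_example_records <- function() {
  mk <- function(id, sbp, dbp, flags) {
    patient_record(
      patient_id = id,
      demographics = list(age = 45L, sex = "male", sbp = sbp, dbp = dbp,
                          bmi = 24.0),
      disease_flags = flags,
      visits = list(list(ordinal = 1, diagnosis_codes = "E11.0",
                         prescription_codes = character(0)))
    )
  }
  list(
    a = mk("A", 145, 95, list(diabetes = TRUE, cerebrovascular = TRUE,
                              ischemic = FALSE)),
    b = mk("B", 150, 105, list(diabetes = FALSE, cerebrovascular = TRUE,
                               ischemic = FALSE))
  )
}

# random valid feature-label bit vector (one-hot per continuous/gender span)
random_feature_bits <- function() {
  bits <- integer(14)
  bits[sample(1:3, 1)] <- 1L
  bits[sample(4:5, 1)] <- 1L
  bits[5 + sample(1:3, 1)] <- 1L
  bits[8 + sample(1:3, 1)] <- 1L
  bits[12:14] <- sample(0:1, 3, replace = TRUE)
  bits
}

# Independent brute-force oracle for category matching, written directly from
# the rule: a one-hot category matches when both patients sit in the same
# group; a disease category matches when both carry the disease.
oracle_match_count <- function(a, b) {
  onehot <- list(1:3, 4:5, 6:8, 9:11)
  m <- sum(vapply(onehot, function(s) which(a[s] == 1) == which(b[s] == 1),
                  logical(1)))
  m + sum(a[12:14] == 1 & b[12:14] == 1)
}

# The directional-replication fixture (500 patients, 2000 pairs, <= 10
# epochs) is expensive; compute it once and share across acceptance tests.
.fixture_env <- new.env(parent = emptyenv())

acceptance_fixture_results <- function() {
  if (!is.null(.fixture_env$results)) return(.fixture_env$results)
  seeds <- c(1, 2, 3)
  out <- list()
  for (s in seeds) {
    cfg <- run_config(seed = s)
    man <- run_pipeline(cfg)
    pairs <- read_pairs_csv(file.path(cfg$out_dir, "pairs.csv"))
    mats <- read_patient_matrices(file.path(cfg$out_dir, "matrices.rds"))
    tc_sim <- train_config(batch_size = 16L, max_epochs = 10L, patience = 10L,
                           learning_rate = 5e-3, seed = s + 40L,
                           loss_weights = c(0, 0, 1))
    m_sim <- train_joint(pairs, mats, enc_cfg = cfg$encoder, tr_cfg = tc_sim)
    ev_sim <- evaluate_joint_model(m_sim, pairs, mats)
    vecs <- t(vapply(mats, patient_vector, numeric(cfg$encoder$embed_dim)))
    rownames(vecs) <- names(mats)
    base_f1 <- vapply(c("euclidean", "cosine", "mahalanobis", "lsml"),
                      function(k) run_baseline(k, vecs, pairs)$report$f1,
                      numeric(1))
    out[[as.character(s)]] <- list(
      joint_f1 = man$metrics$test_f1,
      sim_only_f1 = ev_sim$report$f1,
      baseline_f1 = base_f1
    )
    unlink(cfg$out_dir, recursive = TRUE)
  }
  .fixture_env$results <- out
  out
}
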