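#' Category spans of the 14-bit feature label
#'
#' The feature label is a 14-bit multi-hot vector over 7 categories: age group
#' (3 bits), gender (2), blood-pressure group (3), BMI group (3), and one bit
#' for each of diabetes, cerebrovascular disease and ischemic heart disease.
#'
#' @return named list mapping the 7 category names to their bit indices.
#' @export
feature_category_index <- function() {
  list(age = 1:3, gender = 4:5, bp = 6:8, bmi = 9:11,
       diabetes = 12L, cerebrovascular = 13L, ischemic = 14L)
}

feature_bit_names <- function() {
  c("age_g1", "age_g2", "age_g3", "male", "female",
    "bp_g1", "bp_g2", "bp_g3", "bmi_g1", "bmi_g2", "bmi_g3",
    "diabetes", "cerebrovascular", "ischemic")
}

#' Bin age into three groups
#'
#' Group 1: 0-30 years; group 2: 31-60; group 3: 61 and over.
#'
#' @param age age in whole years, >= 0. Vectorized.
#' @return integer group in {1, 2, 3}.
#' @export
bin_age <- function(age) {
  if (any(is.na(age)) || any(age < 0)) stop("age must be >= 0")
  ifelse(age <= 30, 1L, ifelse(age <= 60, 2L, 3L))
}

#' Bin blood pressure into three groups
#'
#' Staging uses both readings and takes the higher implied stage, the standard
#' clinical convention. Group 1 (prehypertension and below): SBP < 140 and
#' DBP < 90; group 2 (stage 1): SBP 140-159 or DBP 90-99; group 3 (stage 2):
#' SBP >= 160 or DBP >= 100. Readings below the 120/80 prehypertension floor
#' fall in group 1, keeping the partition total.
#'
#' @param sbp systolic pressure, mmHg.
#' @param dbp diastolic pressure, mmHg; requires `sbp > dbp > 0`.
#' @return integer group in {1, 2, 3}.
#' @export
bin_bp <- function(sbp, dbp) {
  if (any(!(sbp > dbp & dbp > 0))) stop("require sbp > dbp > 0")
  s_stage <- ifelse(sbp >= 160, 3L, ifelse(sbp >= 140, 2L, 1L))
  d_stage <- ifelse(dbp >= 100, 3L, ifelse(dbp >= 90, 2L, 1L))
  pmax(s_stage, d_stage)
}

#' Bin body mass index into three groups
#'
#' Group 1 (underweight): below 18.5 kg/m^2; group 2 (normal): 18.5-22.9;
#' group 3 (overweight): 23 and above (Asian-Pacific cut-off).
#'
#' @param bmi body mass index, kg/m^2, > 0.
#' @return integer group in {1, 2, 3}.
#' @export
bin_bmi <- function(bmi) {
  if (any(!(bmi > 0))) stop("bmi must be > 0")
  ifelse(bmi < 18.5, 1L, ifelse(bmi < 23, 2L, 3L))
}

#' Build a patient's 14-bit feature label
#'
#' One-hot encodes age group, gender, BP group and BMI group, and copies the
#' three disease flags, in the fixed bit order given by
#' [feature_category_index()].
#'
#' @param record a `patient_record` (only demographics and disease flags are
#'   used).
#' @return an integer vector of length 14, classed `feature_label`, with bit
#'   names.
#' @export
feature_label <- function(record) {
  d <- record$demographics
  bits <- integer(14)
  bits[bin_age(d$age)] <- 1L
  bits[if (d$sex == "male") 4L else 5L] <- 1L
  bits[5L + bin_bp(d$sbp, d$dbp)] <- 1L
  bits[8L + bin_bmi(d$bmi)] <- 1L
  bits[12:14] <- as.integer(unlist(record$disease_flags[DISEASES]))
  structure(stats::setNames(bits, feature_bit_names()), class = "feature_label")
}

validate_feature_label <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) != 14L || !all(bits %in% 0:1)) {
    stop("a feature label is 14 binary values")
  }
  idx <- feature_category_index()
  for (cat in c("age", "gender", "bp", "bmi")) {
    if (sum(bits[idx[[cat]]]) != 1L) {
      stop(sprintf("exactly one bit must be set in the %s span", cat))
    }
  }
  bits
}

#' Count matching categories between two feature labels
#'
#' A category matches when the two patients share its positive bit: for the
#' one-hot spans (age, gender, BP, BMI) that means the same group; a disease
#' category matches only when both patients carry the disease (two absences
#' do not count as a match). Equivalently, the match count is the number of
#' bits set in both labels. Symmetric, in 0..7.
#'
#' @param a,b feature labels (14-bit vectors).
#' @return integer match count.
#' @export
count_matches <- function(a, b) {
  a <- validate_feature_label(a); b <- validate_feature_label(b)
  sum(a == 1L & b == 1L)
}

#' Binary similarity label from the 4-of-7 category rule
#'
#' Two patients are labeled similar (1) when at least 4 of the 7 feature
#' categories (the median count) match, otherwise dissimilar (0).
#'
#' @param a,b feature labels.
#' @return 0 or 1.
#' @export
similarity_label <- function(a, b) {
  as.integer(count_matches(a, b) >= 4L)
}

cohort_label_table <- function(cohort) {
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  bits <- t(vapply(cohort, function(r) as.integer(feature_label(r)), integer(14)))
  colnames(bits) <- feature_bit_names()
  rownames(bits) <- ids
  bits
}

match_count_from_bits <- function(bits_a, bits_b) {
  sum(bits_a == 1L & bits_b == 1L)
}

#' Sample a labeled patient-pair dataset
#'
#' Draws `n_pairs` distinct unordered patient pairs (no self-pairs, no
#' duplicates after canonicalizing id order), attaches both members' feature
#' labels, the category match count and the binary similarity label, and
#' splits pairs into train/test at `split_ratio` (pair-level split by
#' default; set `patient_disjoint = TRUE` to split patients instead, so that
#' no patient appears in both halves).
#'
#' @param cohort a `patient_cohort`, or a precomputed label table: an
#'   integer matrix with 14 bit columns and patient ids as row names (as from
#'   augmented cohorts).
#' @param n_pairs number of pairs to draw; must not exceed `choose(n, 2)`.
#' @param split_ratio fraction of pairs assigned to training (default 0.8).
#' @param seed integer seed.
#' @param patient_disjoint logical, see above.
#' @return a data.frame with columns `id_a`, `id_b`, `a_*`/`b_*` bit columns,
#'   `match_count`, `sim_label`, `split` ("train"/"test").
#' @export
build_pair_dataset <- function(cohort, n_pairs, split_ratio = 0.8, seed = 1L,
                               patient_disjoint = FALSE) {
  bits <- if (is.matrix(cohort)) cohort else cohort_label_table(cohort)
  n <- nrow(bits)
  if (n < 2L) stop("need at least 2 patients to form pairs")
  if (!is_prob(split_ratio)) stop_config("split_ratio", "must be in [0, 1]")
  ids <- rownames(bits)
  with_seed(seed, {
    if (patient_disjoint) {
      n_tr <- max(2L, round(split_ratio * n))
      tr_pat <- sample.int(n, n_tr)
      te_pat <- setdiff(seq_len(n), tr_pat)
      if (length(te_pat) < 2L) stop("too few patients for a disjoint test split")
      tr_total <- choose(length(tr_pat), 2)
      te_total <- choose(length(te_pat), 2)
      n_tr_pairs <- round(split_ratio * n_pairs)
      n_te_pairs <- n_pairs - n_tr_pairs
      if (n_tr_pairs > tr_total || n_te_pairs > te_total) {
        stop("n_pairs exceeds the number of distinct pairs available per split")
      }
      pk_tr <- decode_pair_index(sample(tr_total, n_tr_pairs), length(tr_pat))
      pk_te <- decode_pair_index(sample(te_total, n_te_pairs), length(te_pat))
      i <- c(tr_pat[pk_tr$i], te_pat[pk_te$i])
      j <- c(tr_pat[pk_tr$j], te_pat[pk_te$j])
      split <- c(rep("train", n_tr_pairs), rep("test", n_te_pairs))
    } else {
      total <- choose(n, 2)
      if (n_pairs > total) {
        stop(sprintf("n_pairs (%d) exceeds the %.0f distinct pairs of %d patients",
                     n_pairs, total, n))
      }
      pk <- decode_pair_index(sample(total, n_pairs), n)
      i <- pk$i; j <- pk$j
      n_tr <- round(split_ratio * n_pairs)
      split <- rep("test", n_pairs)
      split[sample.int(n_pairs, n_tr)] <- "train"
    }
    # canonical id order within the pair
    swap <- ids[i] > ids[j]
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    mc <- vapply(seq_along(i), function(k) match_count_from_bits(bits[i[k], ], bits[j[k], ]),
                 integer(1))
    a_bits <- bits[i, , drop = FALSE]
    b_bits <- bits[j, , drop = FALSE]
    colnames(a_bits) <- paste0("a_", feature_bit_names())
    colnames(b_bits) <- paste0("b_", feature_bit_names())
    df <- data.frame(id_a = ids[i], id_b = ids[j], a_bits, b_bits,
                     match_count = mc, sim_label = as.integer(mc >= 4L),
                     split = split, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
}

# Decode linear indices 1..choose(n,2) into (i < j) pairs, column-major over j.
decode_pair_index <- function(k, n) {
  # pair (i, j), i < j, index = (j-1)(j-2)/2 + i
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  off <- (j - 1) * (j - 2) / 2
  fix <- k <= off
  j[fix] <- j[fix] - 1
  off <- (j - 1) * (j - 2) / 2
  i <- k - off
  list(i = as.integer(i), j = as.integer(j))
}

#' Write / read a pair dataset as CSV
#'
#' @param pairs data.frame from [build_pair_dataset()].
#' @param path file path.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
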