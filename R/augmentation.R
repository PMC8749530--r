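#' Multi-label imbalance report
#'
#' Computes, for each label, the imbalance ratio
#' `IRLbl(l) = max_l' count(l') / count(l)`, their mean (`MeanIR`), and the
#' tail-label set: labels with `IRLbl > MeanIR` (minority labels). Labels with
#' zero positives have undefined IRLbl; they are flagged and excluded from
#' MeanIR.
#'
#' @param labels instance x label binary matrix (column names label the
#'   labels).
#' @return list with `irlbl` (named numeric, NA where undefined), `mean_ir`,
#'   `tail_labels` (character), `counts`, `undefined_labels`.
#' @export
imbalance_report <- function(labels) {
  labels <- as.matrix(labels)
  if (nrow(labels) < 1L) stop("need at least one instance")
  if (is.null(colnames(labels))) colnames(labels) <- paste0("L", seq_len(ncol(labels)))
  counts <- colSums(labels > 0)
  if (all(counts == 0)) stop("need at least one label with a positive instance")
  mx <- max(counts)
  irlbl <- ifelse(counts > 0, mx / counts, NA_real_)
  names(irlbl) <- colnames(labels)
  mean_ir <- mean(irlbl, na.rm = TRUE)
  tail <- names(irlbl)[!is.na(irlbl) & irlbl > mean_ir]
  list(irlbl = irlbl, mean_ir = mean_ir, tail_labels = tail,
       counts = counts, undefined_labels = names(irlbl)[is.na(irlbl)])
}

#' Multi-label SMOTE oversampling
#'
#' For each tail label (IRLbl above MeanIR) and each instance carrying it
#' (the seed instance), picks one of the seed's `k` nearest neighbors among
#' the instances carrying the same tail label (Euclidean distance in feature
#' space) and synthesizes a new instance on the segment between them:
#' `x_new = x_seed + u * (x_neighbor - x_seed)`, `u ~ Uniform(0, 1)`. The
#' synthetic label vector is set by the ranking rule: a label is on iff it is
#' positive in more than half of the seed plus its `k` neighbors. Original
#' instances are preserved; synthetics are appended and flagged.
#'
#' @param features instance x dim numeric feature matrix.
#' @param labels instance x L binary label matrix, rows aligned with
#'   `features`.
#' @param k number of neighbors (default 5); reduced with a warning when a
#'   tail label has too few carriers.
#' @param seed integer seed.
#' @return list with `features`, `labels` (originals plus synthetics),
#'   `synthetic` (logical flag per row), and `parents` (seed/neighbor row
#'   indices per synthetic, NA for originals).
#' @export
mlsmote <- function(features, labels, k = 5L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  stopifnot(nrow(features) == nrow(labels))
  rep0 <- imbalance_report(labels)
  tail <- rep0$tail_labels
  new_f <- list(); new_l <- list(); parents <- list()
  with_seed(seed, {
    for (lab in tail) {
      carriers <- which(labels[, lab] > 0)
      if (length(carriers) < 2L) next  # nothing to interpolate
      k_use <- min(k, length(carriers) - 1L)
      if (k_use < k) {
        warning(sprintf("mlsmote: label '%s' has %d carriers; using k = %d",
                        lab, length(carriers), k_use))
      }
      sub <- features[carriers, , drop = FALSE]
      dd <- as.matrix(stats::dist(sub))
      diag(dd) <- Inf
      for (si in seq_along(carriers)) {
        nn_local <- order(dd[si, ])[seq_len(k_use)]
        pick <- nn_local[sample.int(k_use, 1L)]
        u <- stats::runif(1)
        seed_row <- sub[si, ]
        nb_row <- sub[pick, ]
        x_new <- seed_row + u * (nb_row - seed_row)
        group <- c(carriers[si], carriers[nn_local])
        votes <- colSums(labels[group, , drop = FALSE] > 0)
        l_new <- as.integer(votes > length(group) / 2)
        new_f[[length(new_f) + 1L]] <- x_new
        new_l[[length(new_l) + 1L]] <- l_new
        parents[[length(parents) + 1L]] <- c(seed = carriers[si],
                                             neighbor = carriers[pick], u = u)
      }
    }
  })
  n_syn <- length(new_f)
  if (n_syn > 0L) {
    features <- rbind(features, do.call(rbind, new_f))
    labs2 <- do.call(rbind, new_l)
    colnames(labs2) <- colnames(labels)
    labels <- rbind(labels, labs2)
  }
  list(
    features = features,
    labels = labels,
    synthetic = c(rep(FALSE, nrow(features) - n_syn), rep(TRUE, n_syn)),
    parents = parents
  )
}

#' Patient-level MLSMOTE over a cohort's disease labels
#'
#' Runs [mlsmote()] on the cohort's 3-column disease-label matrix using each
#' patient's mean visit embedding (mean of the real rows of their matrix) as
#' the feature space. Each synthetic patient's full matrix is formed as the
#' same convex combination of the two parents' matrices, row-wise, so
#' synthetics remain valid encoder inputs; their demographics are the same
#' convex combination of the parents' (sex and age rounded from the seed
#' parent's side), and their 14-bit feature labels follow the standard
#' binning rules with disease bits from the MLSMOTE ranking rule.
#'
#' @param cohort a `patient_cohort`.
#' @param matrices named list of `patient_matrix` covering the cohort.
#' @param k,seed passed to [mlsmote()].
#' @return list with `label_table` (bit matrix over original + synthetic
#'   patients, usable by [build_pair_dataset()]), `matrices` (augmented),
#'   `synthetic` (named logical), and `report_before`/`report_after`
#'   imbalance reports on the disease labels.
#' @export
mlsmote_cohort <- function(cohort, matrices, k = 5L, seed = 1L) {
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  feats <- t(vapply(cohort, function(r) {
    pm <- matrices[[r$patient_id]]
    colMeans(pm$matrix[seq_len(pm$n_visits), , drop = FALSE])
  }, numeric(ncol(matrices[[1]]$matrix))))
  dlabels <- t(vapply(cohort, function(r) as.integer(unlist(r$disease_flags[DISEASES])),
                      integer(3)))
  colnames(dlabels) <- DISEASES
  rownames(feats) <- ids
  res <- mlsmote(feats, dlabels, k = k, seed = seed)
  n_orig <- length(cohort)
  n_syn <- sum(res$synthetic)
  bit_tab <- cohort_label_table(cohort)
  mats <- matrices
  if (n_syn > 0L) {
    syn_bits <- matrix(0L, n_syn, 14L, dimnames = list(NULL, feature_bit_names()))
    syn_ids <- sprintf("SYN%05d", seq_len(n_syn))
    for (s in seq_len(n_syn)) {
      par <- res$parents[[s]]
      pa <- cohort[[par[["seed"]]]]; pb <- cohort[[par[["neighbor"]]]]
      u <- par[["u"]]
      mix <- function(f) (1 - u) * pa$demographics[[f]] + u * pb$demographics[[f]]
      age <- as.integer(round(mix("age")))
      sbp <- mix("sbp"); dbp <- mix("dbp"); bmi <- mix("bmi")
      bits <- integer(14)
      bits[bin_age(age)] <- 1L
      bits[if (pa$demographics$sex == "male") 4L else 5L] <- 1L
      bits[5L + bin_bp(sbp, dbp)] <- 1L
      bits[8L + bin_bmi(bmi)] <- 1L
      bits[12:14] <- res$labels[n_orig + s, ]
      syn_bits[s, ] <- bits
      ma <- mats[[pa$patient_id]]; mb <- mats[[pb$patient_id]]
      mm <- (1 - u) * ma$matrix + u * mb$matrix
      mats[[syn_ids[s]]] <- structure(
        list(patient_id = syn_ids[s], matrix = mm,
             n_visits = max(ma$n_visits, mb$n_visits)),
        class = "patient_matrix")
    }
    rownames(syn_bits) <- syn_ids
    bit_tab <- rbind(bit_tab, syn_bits)
  }
  synthetic <- stats::setNames(c(rep(FALSE, n_orig), rep(TRUE, n_syn)), rownames(bit_tab))
  list(
    label_table = bit_tab,
    matrices = mats,
    synthetic = synthetic,
    report_before = imbalance_report(dlabels),
    report_after = imbalance_report(res$labels)
  )
}
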