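disease_combos <- function() {
  list(
    "diabetes+cerebrovascular" = c("diabetes", "cerebrovascular"),
    "diabetes+ischemic" = c("diabetes", "ischemic"),
    "cerebrovascular+ischemic" = c("cerebrovascular", "ischemic"),
    "diabetes+cerebrovascular+ischemic" = c("diabetes", "cerebrovascular", "ischemic")
  )
}

#' Assign pairs to shared-disease combinations
#'
#' A pair belongs to combination C when the set of diseases carried by both
#' members (the intersection of their positive disease bits) equals C. Pairs
#' sharing fewer than two diseases fall into the "unassigned" bucket. Every
#' pair lands in exactly one bucket.
#'
#' @param pairs pair data.frame carrying `a_diabetes`...`b_ischemic` bit
#'   columns (as built by [build_pair_dataset()]).
#' @return factor of bucket names, one per pair.
#' @export
group_pairs_by_disease_combo <- function(pairs) {
  shared <- sapply(DISEASES, function(d) {
    pairs[[paste0("a_", d)]] == 1 & pairs[[paste0("b_", d)]] == 1
  })
  shared <- matrix(shared, nrow = nrow(pairs),
                   dimnames = list(NULL, DISEASES))
  combos <- disease_combos()
  bucket <- rep("unassigned", nrow(pairs))
  for (nm in names(combos)) {
    members <- combos[[nm]]
    hit <- rowSums(shared[, members, drop = FALSE]) == length(members) &
      rowSums(shared) == length(members)
    bucket[hit] <- nm
  }
  factor(bucket, levels = c(names(combos), "unassigned"))
}

#' Summarize similarity scores by disease combination
#'
#' Produces the mean / max / min of pair scores per combination, plus an
#' "average" column: the mean across the four disease combinations of each
#' statistic (the unassigned bucket is excluded from the average).
#'
#' @param pairs pair data.frame.
#' @param scores numeric similarity scores in `[0, 1]`, one per pair.
#' @return data.frame with columns `combination`, `n_pairs`, `mean`, `max`,
#'   `min`; the last row is the cross-combination average.
#' @export
summarize_scores <- function(pairs, scores) {
  stopifnot(length(scores) == nrow(pairs))
  bucket <- group_pairs_by_disease_combo(pairs)
  rows <- lapply(levels(bucket), function(nm) {
    s <- scores[bucket == nm]
    if (length(s) == 0L) {
      data.frame(combination = nm, n_pairs = 0L, mean = NA_real_,
                 max = NA_real_, min = NA_real_)
    } else {
      data.frame(combination = nm, n_pairs = length(s), mean = mean(s),
                 max = max(s), min = min(s))
    }
  })
  out <- do.call(rbind, rows)
  combo_rows <- out$combination != "unassigned"
  avg <- data.frame(combination = "average",
                    n_pairs = sum(out$n_pairs[combo_rows]),
                    mean = mean(out$mean[combo_rows], na.rm = TRUE),
                    max = mean(out$max[combo_rows], na.rm = TRUE),
                    min = mean(out$min[combo_rows], na.rm = TRUE))
  rbind(out, avg)
}

#' Binary classification report
#'
#' Standard confusion-matrix metrics: accuracy, precision, recall and F1 (the
#' harmonic mean of precision and recall). Metrics with a zero denominator
#' are reported as 0 and flagged in `degenerate`.
#'
#' @param predictions,truths equal-length binary vectors.
#' @return list with `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `f1`, `degenerate` (character vector of zero-denominator
#'   metrics).
#' @export
classification_report <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  if (!all(predictions %in% 0:1) || !all(truths %in% 0:1)) {
    stop("predictions and truths must be binary")
  }
  tp <- sum(predictions == 1 & truths == 1)
  fp <- sum(predictions == 1 & truths == 0)
  fn <- sum(predictions == 0 & truths == 1)
  tn <- sum(predictions == 0 & truths == 0)
  degenerate <- character(0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- c(degenerate, "precision"); 0 }
  rec <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- c(degenerate, "recall"); 0 }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
    degenerate <- c(degenerate, "f1"); 0
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(truths),
       precision = prec, recall = rec, f1 = f1, degenerate = degenerate)
}

#' Evaluate a trained joint model on test pairs
#'
#' The model owns two pair-decision channels: the distance channel (Euclidean
#' distance between the two encodings, predicted similar below a threshold)
#' and the feature channel (the expected category-match count
#' `sum_i p_a,i * p_b,i` from the sigmoid head, the learned analogue of the
#' shared-positive-bit rule, predicted similar above a threshold). Both
#' thresholds are chosen on the training pairs by F1 maximization and the
#' channel with the higher training F1 makes the test predictions — a
#' similarity-only ablation, whose head is untrained, falls back to its
#' distance channel automatically, while the full joint model typically uses
#' the feature channel, since a category-overlap relation is not expressible
#' as a single global distance cut. Similarity-score summaries by disease
#' combination always come from the distance channel.
#'
#' @param model a trained `joint_model`.
#' @param pairs pair data.frame with a `split` column.
#' @param matrices named list of `patient_matrix`.
#' @return list with `report` (test classification metrics), `channel`
#'   ("feature" or "distance"), `threshold`, per-channel training F1s,
#'   `score_summary` (test pairs), and `test_scores`.
#' @export
evaluate_joint_model <- function(model, pairs, matrices) {
  dist_of <- function(df) {
    vapply(seq_len(nrow(df)), function(r) {
      pair_distance(model, matrices[[df$id_a[r]]], matrices[[df$id_b[r]]])
    }, numeric(1))
  }
  ids <- unique(c(pairs$id_a, pairs$id_b))
  probs <- lapply(stats::setNames(ids, ids), function(i) {
    predict_feature_probs(model, matrices[[i]])
  })
  match_of <- function(df) {
    vapply(seq_len(nrow(df)), function(r) {
      sum(probs[[df$id_a[r]]] * probs[[df$id_b[r]]])
    }, numeric(1))
  }
  tr <- pairs[pairs$split == "train", , drop = FALSE]
  te <- pairs[pairs$split == "test", , drop = FALSE]
  d_tr <- dist_of(tr)
  th_d <- choose_threshold(d_tr, tr$sim_label, direction = "less")
  m_tr <- match_of(tr)
  th_m <- choose_threshold(m_tr, tr$sim_label, direction = "greater")
  d_te <- dist_of(te)
  if (th_m$f1 > th_d$f1) {
    channel <- "feature"
    pred <- as.integer(match_of(te) > th_m$threshold)
    threshold <- th_m$threshold
  } else {
    channel <- "distance"
    pred <- as.integer(d_te < th_d$threshold)
    threshold <- th_d$threshold
  }
  scores <- similarity_score(d_te, model$train_config$margin)
  list(report = classification_report(pred, te$sim_label),
       channel = channel, threshold = threshold,
       train_f1_distance = th_d$f1, train_f1_feature = th_m$f1,
       score_summary = summarize_scores(te, scores),
       test_scores = scores)
}
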