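#' Flat patient vector for classical metrics
#'
#' The mean of the real (non-padded) visit-embedding rows of a patient
#' matrix; padding rows never contribute.
#'
#' @param pm a `patient_matrix` with at least one real visit.
#' @return numeric vector of length e.
#' @export
patient_vector <- function(pm) {
  if (pm$n_visits < 1L) stop("patient has no real visits")
  colMeans(pm$matrix[seq_len(pm$n_visits), , drop = FALSE])
}

#' Construct a classical metric model
#'
#' `euclidean` and `cosine` need no fitting. `mahalanobis` uses the
#' (ridge-regularized) inverse sample covariance of the training vectors as
#' its matrix M. `lsml` learns M by localized supervised metric learning, see
#' [lsml_fit()].
#'
#' @param kind one of "euclidean", "cosine", "mahalanobis", "lsml".
#' @param vectors training patient vectors (rows), required for the learned
#'   kinds.
#' @param pairs labeled pair data.frame (needed by "lsml").
#' @param ids row names aligning `vectors` with pair ids (defaults to
#'   `rownames(vectors)`).
#' @param ridge regularization added to covariance/scatter diagonals.
#' @param k_local neighbors per point for "lsml".
#' @param shrink identity shrinkage for "lsml", see [lsml_fit()].
#' @return a `metric_model` with fields `kind`, optional `M`, and `threshold`
#'   (NA until [classify_pairs()] or [choose_threshold()] sets it).
#' @export
fit_metric <- function(kind = c("euclidean", "cosine", "mahalanobis", "lsml"),
                       vectors = NULL, pairs = NULL, ids = NULL,
                       ridge = 1e-6, k_local = 5L, shrink = 0) {
  kind <- match.arg(kind)
  M <- NULL
  if (kind == "mahalanobis") {
    if (is.null(vectors)) stop("mahalanobis needs training vectors")
    S <- stats::cov(vectors)
    # shrinkage toward the scaled identity keeps the inverse well conditioned
    S <- S + ridge * mean(diag(S)) * diag(ncol(S))
    M <- inverse_psd(S, 1e-10)
  } else if (kind == "lsml") {
    if (is.null(vectors) || is.null(pairs)) stop("lsml needs vectors and labeled pairs")
    M <- lsml_fit(vectors, pairs, ids = ids %||% rownames(vectors),
                  k_local = k_local, ridge = ridge, shrink = shrink)$M
  }
  structure(list(kind = kind, M = M, threshold = NA_real_), class = "metric_model")
}

# PSD-safe inverse with logged ridge escalation on singular input
inverse_psd <- function(S, ridge) {
  d <- ncol(S)
  for (r in c(ridge, ridge * 100, ridge * 1e4, 1e-2)) {
    Sr <- S + diag(r, d)
    inv <- tryCatch(solve(Sr), error = function(e) NULL)
    if (!is.null(inv)) {
      if (r > ridge) message("covariance singular; ridge raised to ", r)
      return((inv + t(inv)) / 2)
    }
  }
  stop("covariance matrix could not be inverted even with heavy regularization")
}

#' Distance (or cosine similarity) between two patient vectors
#'
#' Euclidean: `||u - v||`; cosine: `u.v / (||u|| ||v||)` (a similarity in
#' `[-1, 1]`, errors on zero vectors); mahalanobis / lsml:
#' `sqrt((u - v)' M (u - v))`.
#'
#' @param model a `metric_model`.
#' @param u,v numeric vectors of equal length.
#' @return scalar distance (>= 0) or cosine similarity.
#' @export
metric_distance <- function(model, u, v) {
  stopifnot(inherits(model, "metric_model"), length(u) == length(v))
  switch(model$kind,
    euclidean = sqrt(sum((u - v)^2)),
    cosine = {
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
      sum(u * v) / (nu * nv)
    },
    {
      if (is.null(model$M)) stop("model must be fitted before computing distances")
      d <- u - v
      q <- drop(crossprod(d, model$M %*% d))
      sqrt(max(q, 0))
    }
  )
}

#' Localized supervised metric learning
#'
#' Learns a PSD Mahalanobis matrix from pair-level similarity labels. For
#' each patient, its `k_local` nearest homogeneous neighbors (patients it is
#' paired with under label 1) and heterogeneous neighbors (label 0), nearest
#' in the raw Euclidean sense, define local within- and between-class scatter
#' matrices; M is assembled from the leading eigenvectors of the whitened
#' between-scatter (generalized eigenproblem `Sb v = lambda Sw v`), scaled by
#' their eigenvalues, so that directions separating dissimilar neighbors are
#' stretched and directions mixing similar neighbors are shrunk.
#'
#' @param vectors n x d matrix of patient vectors, row names = patient ids.
#' @param pairs data.frame with `id_a`, `id_b`, `sim_label`.
#' @param ids optional id vector overriding `rownames(vectors)`.
#' @param k_local neighbors per point on each side (default 5); clamped with
#'   a warning when fewer are available.
#' @param ridge scatter regularization.
#' @param shrink convex shrinkage of the learned matrix toward the identity
#'   (0 = pure scatter solution, 1 = identity/Euclidean); local scatter
#'   matrices estimated from a few hundred patients overfit without it.
#' @param diagonal constrain M to a diagonal matrix (per-dimension
#'   between/within scatter ratios), a heavily regularized member of the
#'   same family that often generalizes better in small samples.
#' @return list with PSD matrix `M` and the `eigenvalues` kept.
#' @export
lsml_fit <- function(vectors, pairs, ids = NULL, k_local = 5L, ridge = 1e-6,
                     shrink = 0, diagonal = FALSE) {
  vectors <- as.matrix(vectors)
  ids <- ids %||% rownames(vectors)
  if (is.null(ids)) stop("vectors must carry patient ids (row names)")
  if (!all(c(0, 1) %in% pairs$sim_label)) {
    stop("lsml needs both similar and dissimilar pairs")
  }
  d <- ncol(vectors)
  idx <- stats::setNames(seq_along(ids), ids)
  ia <- idx[pairs$id_a]; ib <- idx[pairs$id_b]
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]; lab <- pairs$sim_label[keep]
  # adjacency by label
  hom <- split(c(ib[lab == 1], ia[lab == 1]), c(ia[lab == 1], ib[lab == 1]))
  het <- split(c(ib[lab == 0], ia[lab == 0]), c(ia[lab == 0], ib[lab == 0]))
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  n_w <- 0L; n_b <- 0L
  clamped <- FALSE
  local_scatter <- function(i, nbrs, k) {
    nbrs <- unique(nbrs)
    if (length(nbrs) > k) {
      dd <- colSums((t(vectors[nbrs, , drop = FALSE]) - vectors[i, ])^2)
      nbrs <- nbrs[order(dd)[seq_len(k)]]
    }
    S <- matrix(0, d, d)
    for (j in nbrs) {
      df <- vectors[i, ] - vectors[j, ]
      S <- S + tcrossprod(df)
    }
    list(S = S, n = length(nbrs))
  }
  for (i in seq_along(ids)) {
    hi <- hom[[as.character(i)]]; ei <- het[[as.character(i)]]
    if (!is.null(hi)) {
      if (length(unique(hi)) < k_local) clamped <- TRUE
      ls <- local_scatter(i, hi, k_local)
      Sw <- Sw + ls$S; n_w <- n_w + ls$n
    }
    if (!is.null(ei)) {
      if (length(unique(ei)) < k_local) clamped <- TRUE
      ls <- local_scatter(i, ei, k_local)
      Sb <- Sb + ls$S; n_b <- n_b + ls$n
    }
  }
  if (clamped) warning("lsml: fewer than k_local neighbors for some points; clamped")
  Sw <- Sw / max(n_w, 1L)  # mean scatters: homogeneous and heterogeneous
  Sb <- Sb / max(n_b, 1L)  # neighbor counts differ, so normalize by count
  if (diagonal) {
    w <- pmax(diag(Sb) - diag(Sw), 0)
    if (all(w == 0)) w <- rep(1, d)
    w <- w / mean(w)
    M <- diag(w, d)
    if (shrink > 0) M <- (1 - shrink) * M + shrink * diag(1, d)
    return(list(M = M, eigenvalues = w))
  }
  Sw <- Sw + diag(max(ridge, 1e-10) * max(1e-10, mean(diag(Sw))), d)
  # whiten by Sw, eigendecompose whitened Sb
  ew <- eigen(Sw, symmetric = TRUE)
  vals <- pmax(ew$values, max(ew$values) * 1e-10)
  Wm <- ew$vectors %*% diag(1 / sqrt(vals), d) %*% t(ew$vectors)
  B <- Wm %*% Sb %*% Wm
  eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(eb$values, 0)
  keep_r <- lam > max(lam) * 1e-8
  if (!any(keep_r)) {
    # degenerate: no separating direction; fall back to identity direction
    return(list(M = diag(1, d), eigenvalues = rep(1, d)))
  }
  V <- Wm %*% eb$vectors[, keep_r, drop = FALSE]
  M <- V %*% diag(lam[keep_r], sum(keep_r)) %*% t(V)
  M <- (M + t(M)) / 2
  M <- M / mean(diag(M))  # scale-normalize; thresholds absorb scale anyway
  if (shrink > 0) M <- (1 - shrink) * M + shrink * diag(1, d)
  list(M = M, eigenvalues = lam[keep_r])
}

#' Score pairs under a metric model
#'
#' @param model a `metric_model`.
#' @param vectors patient vectors with row names.
#' @param pairs data.frame with `id_a`, `id_b`.
#' @return numeric vector of distances (or cosine similarities).
#' @export
score_pairs <- function(model, vectors, pairs) {
  vapply(seq_len(nrow(pairs)), function(r) {
    metric_distance(model, vectors[pairs$id_a[r], ], vectors[pairs$id_b[r], ])
  }, numeric(1))
}

#' Choose a decision threshold by F1 maximization
#'
#' Scans midpoints of the sorted observed scores and picks the threshold
#' maximizing F1 on the given labels. For distances, pairs below the
#' threshold are predicted similar; for cosine similarities
#' (`direction = "greater"`) pairs above it are.
#'
#' @param scores numeric scores on training pairs.
#' @param labels binary similarity labels.
#' @param direction "less" (distance-like, default) or "greater"
#'   (similarity-like).
#' @return list with `threshold`, `f1`, `direction`.
#' @export
choose_threshold <- function(scores, labels, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) c(s[1] - 1e-9, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1e-9)
          else c(s - 1e-9, s + 1e-9)
  best <- list(threshold = cand[1], f1 = -1, direction = direction)
  for (tau in cand) {
    pred <- if (direction == "less") as.integer(scores < tau) else as.integer(scores > tau)
    f1 <- f1_score(pred, labels)
    if (f1 > best$f1) best <- list(threshold = tau, f1 = f1, direction = direction)
  }
  best
}

f1_score <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Classify pairs with a thresholded metric
#'
#' @param model a `metric_model` whose `threshold` is set (or supply `tau`).
#' @param vectors patient vectors with row names.
#' @param pairs data.frame with `id_a`, `id_b`.
#' @param tau optional threshold overriding `model$threshold`.
#' @return integer predictions (1 = similar).
#' @export
classify_pairs <- function(model, vectors, pairs, tau = NULL) {
  tau <- tau %||% model$threshold
  if (is.na(tau)) stop("no threshold set; run choose_threshold() on training scores")
  scores <- score_pairs(model, vectors, pairs)
  if (model$kind == "cosine") as.integer(scores > tau) else as.integer(scores < tau)
}

#' Fit, threshold and evaluate one baseline end to end
#'
#' Convenience wrapper: fits the metric on training patient vectors, picks
#' the F1-maximizing threshold on training pairs, and reports test-set
#' classification metrics. The learned metrics (mahalanobis, lsml) carry a
#' regularization hyperparameter — covariance shrinkage for Mahalanobis,
#' identity shrinkage of the learned matrix for LSML — whose strength is
#' selected from a small grid on an internal validation slice of the
#' training pairs (scatter matrices estimated from a few hundred patients in
#' tens of dimensions overfit, and training-set F1 cannot see that). Test
#' pairs are never touched during selection.
#'
#' @param kind metric kind, see [fit_metric()].
#' @param vectors patient vectors (rows named by id) covering all pairs.
#' @param pairs pair data.frame with a `split` column.
#' @param k_local passed to [fit_metric()].
#' @param grid candidate regularization strengths: covariance shrinkage
#'   (relative to the mean diagonal) for "mahalanobis", identity shrinkage
#'   in [0, 1] for "lsml".
#' @param val_fraction fraction of training pairs held out for the
#'   hyperparameter choice.
#' @param seed seed for the internal validation split.
#' @return list with `model` (threshold set), `report`
#'   (a [classification_report()]), the chosen `regularization`, and the
#'   training F1.
#' @export
run_baseline <- function(kind, vectors, pairs, k_local = 5L, grid = NULL,
                         val_fraction = 0.25, seed = 1L) {
  tr <- pairs[pairs$split == "train", , drop = FALSE]
  te <- pairs[pairs$split == "test", , drop = FALSE]
  dirn <- if (kind == "cosine") "greater" else "less"
  fit_one <- function(df, reg) {
    switch(kind,
      mahalanobis = fit_metric(kind, vectors = vectors, pairs = df,
                               ridge = reg$ridge),
      lsml = {
        M <- suppressWarnings(
          lsml_fit(vectors, df, k_local = k_local, ridge = 1e-2,
                   shrink = reg$shrink, diagonal = reg$diagonal))$M
        structure(list(kind = "lsml", M = M, threshold = NA_real_),
                  class = "metric_model")
      },
      fit_metric(kind)
    )
  }
  reg_best <- NULL
  if (kind %in% c("mahalanobis", "lsml")) {
    if (is.null(grid)) {
      grid <- if (kind == "mahalanobis") {
        lapply(c(1e-2, 0.1, 1, 10, 100), function(r) list(ridge = r))
      } else {
        c(lapply(c(0, 0.3, 0.6, 0.9), function(s) list(shrink = s, diagonal = FALSE)),
          lapply(c(0, 0.3, 0.6, 0.9, 1), function(s) list(shrink = s, diagonal = TRUE)))
      }
    }
    val_idx <- with_seed(seed, sample.int(nrow(tr), max(1L, round(val_fraction * nrow(tr)))))
    tr_fit <- tr[-val_idx, , drop = FALSE]
    tr_val <- tr[val_idx, , drop = FALSE]
    best_val <- -Inf
    for (reg in grid) {
      model <- fit_one(tr_fit, reg)
      th <- choose_threshold(score_pairs(model, vectors, tr_fit),
                             tr_fit$sim_label, direction = dirn)
      s_val <- score_pairs(model, vectors, tr_val)
      pred_val <- if (dirn == "less") as.integer(s_val < th$threshold)
                  else as.integer(s_val > th$threshold)
      f1_val <- f1_score(pred_val, tr_val$sim_label)
      if (f1_val > best_val) { best_val <- f1_val; reg_best <- reg }
    }
  }
  model <- fit_one(tr, reg_best)
  s_tr <- score_pairs(model, vectors, tr)
  th <- choose_threshold(s_tr, tr$sim_label, direction = dirn)
  model$threshold <- th$threshold
  pred <- classify_pairs(model, vectors, te)
  list(model = model, report = classification_report(pred, te$sim_label),
       train_scores = s_tr, train_f1 = th$f1,
       regularization = reg_best %||% list())
}
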