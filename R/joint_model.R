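#' Encoder architecture configuration
#'
#' The encoder stacks three CNN blocks over the visit axis of a patient
#' matrix. Each block runs three parallel 1-D convolution branches (valid
#' convolution, stride 1, ReLU) with kernel widths `branch_widths` and
#' `block_filters[i]` filters each, max-pools each branch, concatenates the
#' branch channels (temporal lengths aligned by truncation to the shortest
#' branch), applies dropout, then a parameter-free scaled dot-product
#' self-attention with a residual connection. The final feature map is
#' flattened and projected linearly to `output_dim`.
#'
#' @param v_max temporal rows of the input patient matrix (default 200).
#' @param embed_dim channels of the input matrix, the visit-embedding size e
#'   (default 128).
#' @param block_filters filters per block (default `c(128, 64, 32)`).
#' @param branch_widths kernel widths of the parallel branches (default
#'   `c(2, 3, 4)`; width 3 is the reference single-filter setting).
#' @param pool_size max-pooling window (default 2).
#' @param dropout_rate dropout after pooling during training (default 0.3).
#' @param output_dim patient-vector length (default 800).
#' @param attention enable the self-attention module (default TRUE).
#' @param n_labels sigmoid-head width: 14 for the full feature label, 3 for a
#'   disease-only head.
#' @return an `encoder_config`.
#' @export
encoder_config <- function(v_max = 200L, embed_dim = 128L,
                           block_filters = c(128L, 64L, 32L),
                           branch_widths = c(2L, 3L, 4L),
                           pool_size = 2L, dropout_rate = 0.3,
                           output_dim = 800L, attention = TRUE,
                           n_labels = 14L) {
  if (!is_count(output_dim)) stop_config("output_dim", "must be a positive integer")
  if (any(block_filters < 1)) stop_config("block_filters", "all filter counts must be >= 1")
  if (any(branch_widths < 1)) stop_config("branch_widths", "kernel widths must be >= 1")
  if (!is_count(pool_size)) stop_config("pool_size", "must be a positive integer")
  if (!is_prob(dropout_rate)) stop_config("dropout_rate", "must be in [0, 1]")
  cfg <- structure(list(
    v_max = as.integer(v_max), embed_dim = as.integer(embed_dim),
    block_filters = as.integer(block_filters),
    branch_widths = as.integer(branch_widths),
    pool_size = as.integer(pool_size), dropout_rate = dropout_rate,
    output_dim = as.integer(output_dim), attention = isTRUE(attention),
    n_labels = as.integer(n_labels)
  ), class = "encoder_config")
  encoder_shapes(cfg)  # validates temporal lengths
  cfg
}

#' Training configuration for the joint model
#'
#' @param batch_size pairs per mini-batch (default 128).
#' @param max_epochs maximum epochs (default 100).
#' @param patience early-stopping patience on validation total loss
#'   (default 10).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param margin contrastive-loss margin m > 0 (default 1).
#' @param loss_weights length-3 weights for (classification A,
#'   classification B, similarity); `c(1, 1, 1)` is joint learning,
#'   `c(0, 0, 1)` similarity-only, `c(1, 1, 0)` feature-learning-only.
#' @param normalize_embeddings L2-normalize encoder outputs before the
#'   Euclidean distance (default TRUE). Normalization makes the distance a
#'   monotone function of embedding overlap regardless of per-patient vector
#'   norms, which the category-overlap similarity rule requires; distances
#'   then live in `[0, 2]`, commensurate with the default margin. The
#'   classification head always sees the unnormalized vector.
#' @param val_fraction fraction of training pairs held out for early stopping.
#' @param seed integer seed covering initialization, shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 128L, max_epochs = 100L, patience = 10L,
                         learning_rate = 1e-3, margin = 1.0,
                         loss_weights = c(1, 1, 1),
                         normalize_embeddings = TRUE, val_fraction = 0.1,
                         seed = 1L, verbose = FALSE) {
  if (!is.numeric(margin) || margin <= 0) stop_config("margin", "must be > 0")
  if (length(loss_weights) != 3L || any(loss_weights < 0)) {
    stop_config("loss_weights", "must be 3 nonnegative numbers")
  }
  if (!is_prob(val_fraction) || val_fraction >= 1) {
    stop_config("val_fraction", "must be in [0, 1)")
  }
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, margin = margin,
                 loss_weights = loss_weights,
                 normalize_embeddings = isTRUE(normalize_embeddings),
                 val_fraction = val_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

## ---- Losses ----------------------------------------------------------------

#' Binary cross-entropy classification loss
#'
#' `-sum_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]`. Probabilities at exactly
#' 0 or 1 are clamped to `[eps, 1 - eps]`.
#'
#' @param y binary label vector.
#' @param y_hat predicted probabilities, same length.
#' @param eps clamping constant (default 1e-7).
#' @return nonnegative scalar.
#' @export
classification_loss <- function(y, y_hat, eps = 1e-7) {
  stopifnot(length(y) == length(y_hat))
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Contrastive similarity loss
#'
#' `Y * e^2 / 2 + (1 - Y) * max(0, margin - e)^2 / 2`: similar pairs (Y = 1)
#' are pulled toward distance 0, dissimilar pairs pushed beyond the margin.
#'
#' @param Y binary similarity label (1 similar, 0 dissimilar).
#' @param e Euclidean distance between the two patient vectors, >= 0.
#' @param margin margin m > 0.
#' @return nonnegative scalar.
#' @export
contrastive_loss <- function(Y, e, margin = 1.0) {
  if (any(e < 0)) stop("distance e must be >= 0")
  if (margin <= 0) stop("margin must be > 0")
  Y * 0.5 * e^2 + (1 - Y) * 0.5 * pmax(0, margin - e)^2
}

#' Total joint loss
#'
#' Weighted sum of the two classification losses and the similarity loss;
#' default weights (1, 1, 1) reproduce plain summation.
#'
#' @param loss_cls_a,loss_cls_b,loss_sim finite loss components.
#' @param weights length-3 nonnegative weights.
#' @return scalar.
#' @export
joint_loss <- function(loss_cls_a, loss_cls_b, loss_sim, weights = c(1, 1, 1)) {
  comps <- c(cls_a = loss_cls_a, cls_b = loss_cls_b, sim = loss_sim)
  bad <- !is.finite(comps)
  if (any(bad)) {
    stop("non-finite loss component: ", paste(names(comps)[bad], collapse = ", "))
  }
  sum(weights * comps)
}

## ---- Training --------------------------------------------------------------

# per-patient 14-bit labels from the pair table
pair_label_map <- function(pairs, n_labels) {
  a_cols <- grep("^a_", names(pairs), value = TRUE)
  b_cols <- grep("^b_", names(pairs), value = TRUE)
  stopifnot(length(a_cols) >= n_labels, length(b_cols) >= n_labels)
  map <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(pairs))) {
    if (is.null(map[[pairs$id_a[r]]])) {
      map[[pairs$id_a[r]]] <- as.numeric(unlist(pairs[r, a_cols[seq_len(n_labels)]]))
    }
    if (is.null(map[[pairs$id_b[r]]])) {
      map[[pairs$id_b[r]]] <- as.numeric(unlist(pairs[r, b_cols[seq_len(n_labels)]]))
    }
  }
  map
}

# L2 normalization with gradient pass-through: u = z / |z|;
# dz = (du - u (u . du)) / |z|
l2norm_unit <- function(z) {
  n <- sqrt(sum(z^2))
  if (n < 1e-12) list(u = z, n = 1) else list(u = z / n, n = n)
}

# forward + backward for one pair; returns loss components and grads matching
# the param structure
joint_pair_grad <- function(params, cfg, Xa, Xb, ya, yb, Y, margin, w, training,
                            normalize = TRUE) {
  fa <- encoder_forward(params, cfg, Xa, training = training)
  fb <- encoder_forward(params, cfg, Xb, training = training)
  pa <- head_forward(params, fa$z)
  pb <- head_forward(params, fb$z)
  l_a <- classification_loss(ya, pa)
  l_b <- classification_loss(yb, pb)
  if (normalize) {
    na <- l2norm_unit(fa$z); nb <- l2norm_unit(fb$z)
    diff <- na$u - nb$u
  } else {
    diff <- fa$z - fb$z
  }
  e <- sqrt(sum(diff^2))
  l_s <- contrastive_loss(Y, e, margin)
  total <- joint_loss(l_a, l_b, l_s, w)

  # head gradients (scaled by their weights)
  ha <- head_backward(params, fa$z, pa, ya)
  hb <- head_backward(params, fb$z, pb, yb)
  dza <- w[1] * ha$dz
  dzb <- w[2] * hb$dz
  # contrastive gradient w.r.t. embeddings
  if (w[3] > 0) {
    if (Y == 1) {
      g <- diff
    } else {
      g <- if (e < margin && e > 1e-12) -(margin - e) / e * diff else diff * 0
    }
    if (normalize) {
      ga_u <- w[3] * g
      gb_u <- -w[3] * g
      dza <- dza + (ga_u - na$u * sum(na$u * ga_u)) / na$n
      dzb <- dzb + (gb_u - nb$u * sum(nb$u * gb_u)) / nb$n
    } else {
      dza <- dza + w[3] * g
      dzb <- dzb - w[3] * g
    }
  }
  ga <- encoder_backward(params, cfg, fa, dza)
  gb <- encoder_backward(params, cfg, fb, dzb)
  grads <- list(
    blocks = params_map2(ga$blocks, gb$blocks, `+`),
    dense_W = ga$dense_W + gb$dense_W,
    dense_b = ga$dense_b + gb$dense_b,
    head_W = w[1] * ha$head_W + w[2] * hb$head_W,
    head_b = w[1] * ha$head_b + w[2] * hb$head_b
  )
  list(grads = grads, total = total, l_a = l_a, l_b = l_b, l_s = l_s)
}

joint_pair_loss <- function(params, cfg, Xa, Xb, ya, yb, Y, margin, w,
                            normalize = TRUE) {
  fa <- encoder_forward(params, cfg, Xa, training = FALSE)
  fb <- encoder_forward(params, cfg, Xb, training = FALSE)
  l_a <- classification_loss(ya, head_forward(params, fa$z))
  l_b <- classification_loss(yb, head_forward(params, fb$z))
  za <- fa$z; zb <- fb$z
  if (normalize) {
    za <- l2norm_unit(za)$u; zb <- l2norm_unit(zb)$u
  }
  e <- sqrt(sum((za - zb)^2))
  joint_loss(l_a, l_b, contrastive_loss(Y, e, margin), w)
}

#' Train the joint similarity model
#'
#' Trains a weight-shared encoder on patient pairs: both members pass through
#' the same CNN encoder; each patient vector feeds a sigmoid head scored by
#' binary cross-entropy against the patient's feature-label bits, and the
#' Euclidean distance between the two vectors feeds the contrastive loss. The
#' weighted sum of the three terms is minimized by mini-batch Adam with early
#' stopping on a held-out validation slice of the training pairs.
#'
#' @param pairs pair data.frame from [build_pair_dataset()]; rows with
#'   `split == "train"` are used.
#' @param matrices named list of `patient_matrix` covering all paired ids.
#' @param enc_cfg an [encoder_config()]; its `v_max`/`embed_dim` must match
#'   the matrices.
#' @param tr_cfg a [train_config()].
#' @return a `joint_model`: parameters, both configs, and a per-epoch
#'   `history` data.frame (`epoch`, `train_total`, `train_cls`, `train_sim`,
#'   `val_total`).
#' @export
train_joint <- function(pairs, matrices, enc_cfg = encoder_config(),
                        tr_cfg = train_config()) {
  train_rows <- which(pairs$split == "train")
  if (length(train_rows) == 0L) stop("no training pairs (split == 'train')")
  pm0 <- matrices[[pairs$id_a[train_rows[1]]]]
  if (nrow(pm0$matrix) != enc_cfg$v_max || ncol(pm0$matrix) != enc_cfg$embed_dim) {
    stop(sprintf("matrix shape %dx%d does not match encoder config %dx%d",
                 nrow(pm0$matrix), ncol(pm0$matrix), enc_cfg$v_max, enc_cfg$embed_dim))
  }
  labmap <- pair_label_map(pairs, enc_cfg$n_labels)
  w <- tr_cfg$loss_weights
  with_seed(tr_cfg$seed, {
    params <- init_joint_params(enc_cfg)
    opt <- adam_init(params)
    n_val <- floor(tr_cfg$val_fraction * length(train_rows))
    val_rows <- if (n_val > 0) sample(train_rows, n_val) else integer(0)
    fit_rows <- setdiff(train_rows, val_rows)
    history <- data.frame()
    best_val <- Inf; best_params <- params; wait <- 0L
    for (epoch in seq_len(tr_cfg$max_epochs)) {
      ord <- sample(fit_rows)
      ep_tot <- ep_cls <- ep_sim <- 0
      batches <- split(ord, ceiling(seq_along(ord) / tr_cfg$batch_size))
      for (bt in batches) {
        acc <- NULL
        b_tot <- 0
        for (r in bt) {
          pa <- matrices[[pairs$id_a[r]]]; pb <- matrices[[pairs$id_b[r]]]
          res <- joint_pair_grad(params, enc_cfg, pa$matrix, pb$matrix,
                                 labmap[[pairs$id_a[r]]], labmap[[pairs$id_b[r]]],
                                 pairs$sim_label[r], tr_cfg$margin, w,
                                 training = TRUE,
                                 normalize = tr_cfg$normalize_embeddings)
          acc <- if (is.null(acc)) res$grads else params_map2(acc, res$grads, `+`)
          b_tot <- b_tot + res$total
          ep_tot <- ep_tot + res$total
          ep_cls <- ep_cls + w[1] * res$l_a + w[2] * res$l_b
          ep_sim <- ep_sim + w[3] * res$l_s
        }
        if (!is.finite(b_tot)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d; %s",
                       epoch, "lower the learning rate or loss weights"))
        }
        acc <- params_map(acc, function(g) g / length(bt))
        st <- adam_step(params, acc, opt, tr_cfg$learning_rate)
        params <- st$params; opt <- st$state
      }
      n_fit <- length(fit_rows)
      val_total <- if (length(val_rows)) {
        mean(vapply(val_rows, function(r) {
          joint_pair_loss(params, enc_cfg,
                          matrices[[pairs$id_a[r]]]$matrix,
                          matrices[[pairs$id_b[r]]]$matrix,
                          labmap[[pairs$id_a[r]]], labmap[[pairs$id_b[r]]],
                          pairs$sim_label[r], tr_cfg$margin, w,
                          normalize = tr_cfg$normalize_embeddings)
        }, numeric(1)))
      } else ep_tot / n_fit
      history <- rbind(history, data.frame(
        epoch = epoch, train_total = ep_tot / n_fit, train_cls = ep_cls / n_fit,
        train_sim = ep_sim / n_fit, val_total = val_total))
      if (tr_cfg$verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        ep_tot / n_fit, val_total))
      }
      if (val_total < best_val - 1e-6) {
        best_val <- val_total; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tr_cfg$patience) break
      }
    }
    structure(list(params = best_params, encoder_config = enc_cfg,
                   train_config = tr_cfg, history = history, trained = TRUE),
              class = "joint_model")
  })
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("<joint_model: %d epochs trained, output_dim %d, final val loss %.4f>\n",
              nrow(x$history), x$encoder_config$output_dim,
              utils::tail(x$history$val_total, 1)))
  invisible(x)
}

#' Encode a patient matrix into the model's vector space
#'
#' @param model a trained `joint_model`.
#' @param pm a `patient_matrix` (or bare numeric matrix) of the configured
#'   shape.
#' @return numeric vector of length `output_dim`.
#' @export
encode_patient <- function(model, pm) {
  stopifnot(inherits(model, "joint_model"), isTRUE(model$trained))
  X <- if (inherits(pm, "patient_matrix")) pm$matrix else pm
  cfg <- model$encoder_config
  if (nrow(X) != cfg$v_max || ncol(X) != cfg$embed_dim) {
    stop(sprintf("input is %dx%d but the encoder expects %dx%d",
                 nrow(X), ncol(X), cfg$v_max, cfg$embed_dim))
  }
  encoder_forward(model$params, cfg, X, training = FALSE)$z
}

#' Predicted feature-label probabilities for a patient
#'
#' @inheritParams encode_patient
#' @return probabilities of length `n_labels`.
#' @export
predict_feature_probs <- function(model, pm) {
  head_forward(model$params, encode_patient(model, pm))
}

#' Pair distance and similarity score
#'
#' `pair_distance` is the Euclidean distance between the two encoded patient
#' vectors (L2-normalized first when the model was trained with
#' `normalize_embeddings`, the default). `similarity_score` maps a distance
#' to `[0, 1]` by `1 - min(e, margin) / margin`: 1 at distance zero, 0 at or
#' beyond the margin, monotone in between.
#'
#' @param model a trained `joint_model`.
#' @param pm_a,pm_b patient matrices.
#' @return `pair_distance`: nonnegative scalar.
#' @export
pair_distance <- function(model, pm_a, pm_b) {
  za <- encode_patient(model, pm_a)
  zb <- encode_patient(model, pm_b)
  if (isTRUE(model$train_config$normalize_embeddings)) {
    za <- l2norm_unit(za)$u
    zb <- l2norm_unit(zb)$u
  }
  sqrt(sum((za - zb)^2))
}

#' @rdname pair_distance
#' @param e distance(s) >= 0.
#' @param margin margin used by the trained model (default 1).
#' @export
similarity_score <- function(e, margin = 1.0) {
  if (any(e < 0)) stop("distance must be >= 0")
  1 - pmin(e, margin) / margin
}
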