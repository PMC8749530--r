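#' Build visit documents from a patient record
#'
#' Each visit becomes one document: an ordered token list holding the sex
#' token, the age-group token, the visit's diagnosis codes and its
#' prescription codes. Documents preserve visit order and are deterministic.
#'
#' @param record a `patient_record`.
#' @return list of `visit_document` objects (`patient_id`, `ordinal`,
#'   `tokens`).
#' @export
build_visit_documents <- function(record) {
  sex_tok <- paste0("SEX:", record$demographics$sex)
  age_tok <- paste0("AGEGRP:", bin_age(record$demographics$age))
  lapply(record$visits, function(v) {
    structure(list(
      patient_id = record$patient_id,
      ordinal = v$ordinal,
      tokens = c(sex_tok, age_tok, v$diagnosis_codes, v$prescription_codes)
    ), class = "visit_document")
  })
}

#' Train a visit embedder
#'
#' Two interchangeable backends map a visit document to a fixed-length real
#' vector:
#'
#' * `"pvdm"`: a distributed-memory paragraph-vector model. Each document
#'   (visit) owns a paragraph vector; the model predicts each token from the
#'   average of the paragraph vector and the context-window token vectors via
#'   a full softmax over the vocabulary (practical here because synthetic code
#'   vocabularies are small). Unseen documents are embedded by gradient
#'   inference with frozen token vectors.
#' * `"hash"`: a training-free deterministic projection; each token is hashed
#'   to a coordinate and sign, and a document embeds as the normalized signed
#'   sum of its token indicators. Useful as a fast, exactly reproducible
#'   fixture backend.
#'
#' @param corpus non-empty list of `visit_document`s.
#' @param dim embedding dimension e (default 128).
#' @param seed integer seed (pvdm initialization and epoch shuffling).
#' @param backend `"pvdm"` or `"hash"`.
#' @param window context window half-width for pvdm (default 5).
#' @param epochs training epochs for pvdm (default 40).
#' @param min_count minimum token frequency kept in the pvdm vocabulary.
#' @param learning_rate initial SGD learning rate for pvdm, linearly decayed.
#' @return an `embedder` object with `backend`, `dim` and backend state.
#' @export
train_embedder <- function(corpus, dim = 128L, seed = 1L,
                           backend = c("pvdm", "hash"),
                           window = 5L, epochs = 40L, min_count = 1L,
                           learning_rate = 0.05) {
  backend <- match.arg(backend)
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  if (!is_count(dim)) stop_config("dim", "must be a positive integer")
  emb <- list(backend = backend, dim = as.integer(dim), trained = TRUE)
  if (backend == "pvdm") {
    emb$model <- pvdm_train(corpus, dim = as.integer(dim), seed = seed,
                            window = as.integer(window), epochs = as.integer(epochs),
                            min_count = as.integer(min_count), lr = learning_rate)
    emb$infer_epochs <- 20L
    emb$infer_seed <- as.integer(seed)
  }
  structure(emb, class = "embedder")
}

#' @export
print.embedder <- function(x, ...) {
  cat(sprintf("<embedder backend=%s dim=%d>\n", x$backend, x$dim))
  invisible(x)
}

#' Embed one visit document
#'
#' @param embedder an `embedder` from [train_embedder()].
#' @param doc a `visit_document`.
#' @return numeric vector of length `embedder$dim`.
#' @export
embed_visit <- function(embedder, doc) {
  stopifnot(inherits(embedder, "embedder"))
  if (embedder$backend == "hash") {
    hash_embed_tokens(doc$tokens, embedder$dim)
  } else {
    pvdm_infer(embedder$model, doc$tokens, epochs = embedder$infer_epochs,
               seed = embedder$infer_seed)
  }
}

# Signed feature hashing: token -> (coordinate, sign); document vector is the
# signed count vector scaled by 1/sqrt(n_tokens) so lengths are comparable
# across visits with different token counts.
hash_embed_tokens <- function(tokens, dim) {
  v <- numeric(dim)
  if (length(tokens) == 0L) return(v)
  for (tok in tokens) {
    h <- fnv1a32(tok)
    idx <- (h %% dim) + 1
    sgn <- if (fnv1a32(paste0("#", tok)) %% 2 == 0) 1 else -1
    v[idx] <- v[idx] + sgn
  }
  v / sqrt(length(tokens))
}

## ---- PV-DM ----------------------------------------------------------------

pvdm_train <- function(corpus, dim, seed, window, epochs, min_count, lr) {
  toks <- lapply(corpus, `[[`, "tokens")
  freq <- table(unlist(toks, use.names = FALSE))
  vocab <- names(freq)[freq >= min_count]
  if (length(vocab) == 0L) stop("pvdm vocabulary is empty after min_count filtering")
  V <- length(vocab)
  docs <- lapply(toks, function(tt) match(tt, vocab))
  with_seed(seed, {
    W <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)  # input token vectors
    D <- matrix(stats::runif(length(docs) * dim, -0.5, 0.5) / dim, length(docs), dim)
    U <- matrix(0, V, dim)                                        # softmax weights
    n_steps <- epochs * length(docs)
    step <- 0L
    for (ep in seq_len(epochs)) {
      order_docs <- sample.int(length(docs))
      for (di in order_docs) {
        step <- step + 1L
        cur_lr <- lr * max(1 - step / n_steps, 1e-4)
        ids <- docs[[di]][!is.na(docs[[di]])]
        if (length(ids) == 0L) next
        D[di, ] <- pvdm_doc_pass(ids, D[di, ], W, U, window, cur_lr,
                                 update_words = TRUE, env = environment())
      }
    }
    structure(list(vocab = vocab, W = W, U = U, dim = dim, window = window, lr = lr),
              class = "pvdm_model")
  })
}

# One pass over a document: for each position, predict the center token from
# the mean of the paragraph vector and the context token vectors (full
# softmax). Updates U and (optionally) W in the enclosing environment via
# `env`; returns the updated paragraph vector.
pvdm_doc_pass <- function(ids, dvec, W, U, window, lr, update_words, env) {
  n <- length(ids)
  for (t in seq_len(n)) {
    lo <- max(1L, t - window); hi <- min(n, t + window)
    ctx <- ids[setdiff(lo:hi, t)]
    h <- if (length(ctx)) (dvec + colSums(W[ctx, , drop = FALSE])) / (1 + length(ctx))
         else dvec
    scores <- as.vector(U %*% h)
    scores <- scores - max(scores)
    p <- exp(scores); p <- p / sum(p)
    p[ids[t]] <- p[ids[t]] - 1           # softmax gradient (p - y)
    dh <- as.vector(crossprod(U, p))
    if (update_words) {
      env$U <- env$U - lr * tcrossprod(p, h)
      if (length(ctx)) {
        g <- lr * dh / (1 + length(ctx))
        env$W[ctx, ] <- env$W[ctx, , drop = FALSE] - matrix(g, length(ctx), length(g), byrow = TRUE)
      }
      dvec <- dvec - lr * dh / (1 + max(length(ctx), 0))
      # re-read shared matrices for the next position
      W <- env$W; U <- env$U
    } else {
      dvec <- dvec - lr * dh / (1 + length(ctx))
    }
  }
  dvec
}

pvdm_infer <- function(model, tokens, epochs = 20L, seed = 1L) {
  ids <- match(tokens, model$vocab)
  ids <- ids[!is.na(ids)]
  dvec <- numeric(model$dim)
  if (length(ids) == 0L) return(dvec)
  for (ep in seq_len(epochs)) {
    cur_lr <- model$lr * max(1 - ep / epochs, 0.05)
    dvec <- pvdm_doc_pass(ids, dvec, model$W, model$U, model$window, cur_lr,
                          update_words = FALSE, env = NULL)
  }
  dvec
}

## ---- Patient matrices -----------------------------------------------------

#' Assemble a zero-padded patient matrix
#'
#' Stacks the embeddings of a patient's visits, in visit order, as the first
#' `v` rows of a `v_max x e` matrix; rows beyond the real visit count are
#' exactly zero. Defaults give the 200 x 128 representation.
#'
#' @param record a `patient_record` with between 1 and `v_max` visits (run
#'   [apply_exclusion_filters()] first).
#' @param embedder an `embedder`.
#' @param v_max maximum number of visits / matrix rows (default 200).
#' @return a `patient_matrix`: list with `patient_id`, `matrix` (v_max x e),
#'   `n_visits`.
#' @export
build_patient_matrix <- function(record, embedder, v_max = 200L) {
  n_v <- length(record$visits)
  if (n_v < 1L) stop("record has no visits")
  if (n_v > v_max) {
    stop(sprintf("record %s has %d visits > v_max = %d; apply exclusion filters first",
                 record$patient_id, n_v, v_max))
  }
  docs <- build_visit_documents(record)
  m <- matrix(0, nrow = v_max, ncol = embedder$dim)
  for (v in seq_len(n_v)) m[v, ] <- embed_visit(embedder, docs[[v]])
  structure(list(patient_id = record$patient_id, matrix = m, n_visits = n_v),
            class = "patient_matrix")
}

#' @export
print.patient_matrix <- function(x, ...) {
  cat(sprintf("<patient_matrix %s: %d x %d, %d real visits>\n",
              x$patient_id, nrow(x$matrix), ncol(x$matrix), x$n_visits))
  invisible(x)
}

#' Build matrices for a whole cohort
#'
#' @param cohort a `patient_cohort`.
#' @inheritParams build_patient_matrix
#' @return named list of `patient_matrix`, keyed by patient id.
#' @export
build_cohort_matrices <- function(cohort, embedder, v_max = 200L) {
  out <- lapply(cohort, build_patient_matrix, embedder = embedder, v_max = v_max)
  names(out) <- vapply(cohort, `[[`, character(1), "patient_id")
  out
}

#' Persist / load patient matrices
#'
#' Matrices are stored in a single R-native serialization file together with
#' their ids, real visit counts and the shared (v_max, e) shape.
#'
#' @param matrices named list of `patient_matrix`.
#' @param path file path (conventionally `.rds`).
#' @export
write_patient_matrices <- function(matrices, path) {
  saveRDS(matrices, path)
  invisible(path)
}

#' @rdname write_patient_matrices
#' @export
read_patient_matrices <- function(path) {
  readRDS(path)
}
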