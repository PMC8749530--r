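# Internal neural-network primitives for the joint similarity model.
# All layers operate on one sample: a T x C matrix (time/visit axis by
# channels). Each forward returns its output plus the cache its backward
# needs; backwards return gradients of the same shapes as their inputs.

## ---- 1-D convolution (valid, stride 1) ------------------------------------

# Unfold X (T x C) into windows of width h: (T-h+1) x (h*C)
im2col <- function(X, h) {
  Tn <- nrow(X)
  Tp <- Tn - h + 1L
  cols <- vector("list", h)
  for (j in seq_len(h)) cols[[j]] <- X[j:(Tp + j - 1L), , drop = FALSE]
  do.call(cbind, cols)
}

conv1d_forward <- function(X, W, b) {
  h <- attr(W, "kernel_width")
  M <- im2col(X, h)
  Z <- sweep(M %*% W, 2L, b, `+`)
  A <- Z * (Z > 0)  # ReLU
  list(out = A, cache = list(M = M, Z = Z, h = h, Tin = nrow(X), Cin = ncol(X)))
}

conv1d_backward <- function(dA, W, cache) {
  dZ <- dA * (cache$Z > 0)
  dW <- crossprod(cache$M, dZ)
  attr(dW, "kernel_width") <- cache$h
  db <- colSums(dZ)
  dM <- dZ %*% t(W)
  dX <- matrix(0, cache$Tin, cache$Cin)
  Tp <- nrow(dZ)
  C <- cache$Cin
  for (j in seq_len(cache$h)) {
    idx <- ((j - 1L) * C + 1L):(j * C)
    rows <- j:(Tp + j - 1L)
    dX[rows, ] <- dX[rows, ] + dM[, idx, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- Max pooling (non-overlapping) ----------------------------------------

maxpool_forward <- function(X, p) {
  Tn <- nrow(X); Fc <- ncol(X)
  To <- Tn %/% p
  if (To < 1L) stop("feature map too short for pooling")
  out <- X[seq(1L, by = p, length.out = To), , drop = FALSE]
  arg <- matrix(1L, To, Fc)
  if (p > 1L) {
    for (r in 2:p) {
      cand <- X[seq(r, by = p, length.out = To), , drop = FALSE]
      upd <- cand > out
      out[upd] <- cand[upd]
      arg[upd] <- r
    }
  }
  list(out = out, cache = list(arg = arg, p = p, Tin = Tn, Fc = Fc))
}

maxpool_backward <- function(dOut, cache) {
  To <- nrow(dOut)
  dX <- matrix(0, cache$Tin, cache$Fc)
  base <- (seq_len(To) - 1L) * cache$p
  for (f in seq_len(cache$Fc)) {
    rows <- base + cache$arg[, f]
    dX[rows, f] <- dOut[, f]
  }
  dX
}

## ---- Scaled dot-product self-attention with residual ----------------------

# Y = X + softmax(X X' / sqrt(C)) X. Parameter-free single head over the
# temporal axis; rows of the attention matrix are nonnegative and sum to 1.
attention_forward <- function(X) {
  C <- ncol(X)
  s <- sqrt(C)
  S <- tcrossprod(X) / s
  S <- S - apply(S, 1L, max)
  A <- exp(S)
  A <- A / rowSums(A)
  Y <- X + A %*% X
  list(out = Y, cache = list(A = A, X = X, s = s))
}

attention_backward <- function(dY, cache) {
  A <- cache$A; X <- cache$X; s <- cache$s
  dX <- dY                      # residual path
  dA <- tcrossprod(dY, X)       # dY %*% t(X)
  dX <- dX + crossprod(A, dY)   # t(A) %*% dY
  dS <- A * (dA - rowSums(dA * A))
  dX <- dX + (dS %*% X + crossprod(dS, X)) / s
  dX
}

## ---- Dropout ---------------------------------------------------------------

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

## ---- Parameter initialization ---------------------------------------------

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(prod(dims), -lim, lim), dims[1], dims[2])
}

# Trace the temporal length through the blocks; errors if the map collapses.
encoder_shapes <- function(cfg) {
  Tn <- cfg$v_max; C <- cfg$embed_dim
  shapes <- list()
  for (bi in seq_along(cfg$block_filters)) {
    Fb <- cfg$block_filters[bi]
    lens <- integer(length(cfg$branch_widths))
    for (wi in seq_along(cfg$branch_widths)) {
      h <- cfg$branch_widths[wi]
      if (h > Tn) stop(sprintf("kernel width %d exceeds temporal length %d in block %d",
                               h, Tn, bi))
      lc <- Tn - h + 1L
      lens[wi] <- lc %/% cfg$pool_size
      if (lens[wi] < 1L) stop(sprintf("block %d branch %d pools to length 0", bi, wi))
    }
    Tmin <- min(lens)
    shapes[[bi]] <- list(Cin = C, Fb = Fb, Tout = Tmin)
    Tn <- Tmin
    C <- Fb * length(cfg$branch_widths)
  }
  list(blocks = shapes, flat = Tn * C, Tfinal = Tn, Cfinal = C)
}

init_joint_params <- function(cfg) {
  sh <- encoder_shapes(cfg)
  blocks <- vector("list", length(cfg$block_filters))
  Cin <- cfg$embed_dim
  for (bi in seq_along(cfg$block_filters)) {
    Fb <- cfg$block_filters[bi]
    branch <- vector("list", length(cfg$branch_widths))
    for (wi in seq_along(cfg$branch_widths)) {
      h <- cfg$branch_widths[wi]
      W <- glorot(h * Cin, Fb, c(h * Cin, Fb))
      attr(W, "kernel_width") <- h
      branch[[wi]] <- list(W = W, b = numeric(Fb))
    }
    blocks[[bi]] <- branch
    Cin <- Fb * length(cfg$branch_widths)
  }
  list(
    blocks = blocks,
    dense_W = glorot(sh$flat, cfg$output_dim, c(sh$flat, cfg$output_dim)),
    dense_b = numeric(cfg$output_dim),
    head_W = glorot(cfg$output_dim, cfg$n_labels, c(cfg$output_dim, cfg$n_labels)),
    head_b = numeric(cfg$n_labels)
  )
}

## ---- Encoder forward / backward -------------------------------------------

encoder_forward <- function(params, cfg, X, training = FALSE) {
  caches <- vector("list", length(params$blocks))
  for (bi in seq_along(params$blocks)) {
    branch_out <- list(); branch_cache <- list()
    lens <- integer(length(params$blocks[[bi]]))
    for (wi in seq_along(params$blocks[[bi]])) {
      pr <- params$blocks[[bi]][[wi]]
      cv <- conv1d_forward(X, pr$W, pr$b)
      pl <- maxpool_forward(cv$out, cfg$pool_size)
      branch_out[[wi]] <- pl$out
      branch_cache[[wi]] <- list(conv = cv$cache, pool = pl$cache)
      lens[wi] <- nrow(pl$out)
    }
    Tmin <- min(lens)
    cat_out <- do.call(cbind, lapply(branch_out, function(m) m[seq_len(Tmin), , drop = FALSE]))
    dp <- dropout_forward(cat_out, cfg$dropout_rate, training)
    at <- if (cfg$attention) attention_forward(dp$out) else list(out = dp$out, cache = NULL)
    caches[[bi]] <- list(branches = branch_cache, lens = lens, Tmin = Tmin,
                         drop = dp$cache, attn = at$cache,
                         Fb = ncol(branch_out[[1]]))
    X <- at$out
  }
  flat <- as.vector(X)
  z <- as.vector(crossprod(params$dense_W, flat)) + params$dense_b
  list(z = z, caches = caches, flat = flat, final_dim = dim(X))
}

encoder_backward <- function(params, cfg, fwd, dz) {
  grads <- list(blocks = vector("list", length(params$blocks)))
  grads$dense_W <- tcrossprod(fwd$flat, dz)
  grads$dense_b <- dz
  dflat <- as.vector(params$dense_W %*% dz)
  dX <- matrix(dflat, fwd$final_dim[1], fwd$final_dim[2])
  for (bi in rev(seq_along(params$blocks))) {
    ch <- fwd$caches[[bi]]
    if (cfg$attention) dX <- attention_backward(dX, ch$attn)
    dX <- dropout_backward(dX, ch$drop)
    nb <- length(params$blocks[[bi]])
    Fb <- ch$Fb
    dX_in <- NULL
    gb <- vector("list", nb)
    for (wi in seq_len(nb)) {
      cols <- ((wi - 1L) * Fb + 1L):(wi * Fb)
      d_branch <- matrix(0, ch$lens[wi], Fb)
      d_branch[seq_len(ch$Tmin), ] <- dX[, cols, drop = FALSE]
      d_pool <- maxpool_backward(d_branch, ch$branches[[wi]]$pool)
      bk <- conv1d_backward(d_pool, params$blocks[[bi]][[wi]]$W, ch$branches[[wi]]$conv)
      gb[[wi]] <- list(W = bk$dW, b = bk$db)
      dX_in <- if (is.null(dX_in)) bk$dX else dX_in + bk$dX
    }
    grads$blocks[[bi]] <- gb
    dX <- dX_in
  }
  grads$dX_input <- dX
  grads
}

head_forward <- function(params, z) {
  logits <- as.vector(crossprod(params$head_W, z)) + params$head_b
  1 / (1 + exp(-logits))
}

# gradient of summed BCE w.r.t. logits is (p - y)
head_backward <- function(params, z, p, y) {
  dlogit <- p - y
  list(head_W = tcrossprod(z, dlogit), head_b = dlogit,
       dz = as.vector(params$head_W %*% dlogit))
}

## ---- Parameter arithmetic (flat traversal) --------------------------------

params_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(params_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else {
    r <- f(a, b)
    attributes(r) <- attributes(a)
    r
  }
}

params_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, params_map, f = f)
    attributes(out) <- attributes(a)
    out
  } else {
    r <- f(a)
    attributes(r) <- attributes(a)
    r
  }
}

params_zero_like <- function(a) params_map(a, function(x) x * 0)

params_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, params_flatten), use.names = FALSE) else as.vector(a)
}

params_unflatten <- function(template, v) {
  pos <- 0L
  rec <- function(a) {
    if (is.list(a)) {
      out <- lapply(a, rec)
      attributes(out) <- attributes(a)
      out
    } else {
      n <- length(a)
      r <- v[(pos + 1L):(pos + n)]
      pos <<- pos + n
      dim(r) <- dim(a)
      attributes(r) <- attributes(a)
      r
    }
  }
  rec(template)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = params_zero_like(params), v = params_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- params_map2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- params_map2(params, upd, `-`)
  list(params = params, state = state)
}
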