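#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' Run an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package route through this helper so that
#' a seeded call never disturbs the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("seed", "must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stable 32-bit FNV-1a hash of a character string, returned as a double in
# [0, 2^32). Pure integer arithmetic below 2^53, so identical on every
# platform; used by the hashing embedder and for config fingerprints.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b %% 256)
    # h * 16777619 mod 2^32 without exceeding 2^53: split h into halves
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * 16777619) %% 4294967296 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; map via modular split to stay unsigned
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(ah, bh) * 65536 + bitwXor(al, bl)
}

# Deterministic fingerprint of an R object (config hashing for manifests).
object_fingerprint <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  h <- fnv1a32(txt)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}
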