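# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing stochastic operations route their seeds through this so a
# master seed fully determines every output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  force(expr)
}

# Deterministically derive a child seed from a parent seed and stream index.
# Kept strictly below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483629
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 30269 + 11) %% 2147483629
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Pairwise squared Euclidean distances between rows of a (n x d) and b (m x d).
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
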