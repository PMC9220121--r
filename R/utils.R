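# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generation inside the
#' package never disturbs the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(expr)
}

# Derive a child seed from a run seed and a stream label; stays below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L)
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# leaky ReLU and its derivative mask
lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable softmax over columns of a matrix (classes in rows).
softmax_cols <- function(x) {
  x <- sweep(x, 2L, apply(x, 2L, max), "-")
  e <- exp(x)
  sweep(e, 2L, colSums(e), "/")
}

# log-softmax over columns
log_softmax_cols <- function(x) {
  x <- sweep(x, 2L, apply(x, 2L, max), "-")
  sweep(x, 2L, log(colSums(exp(x))), "-")
}
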