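# Internal helpers shared across modules.

#' Largest-remainder integer allocation
#'
#' Splits `n` units among categories with target fractions `p` (summing to 1):
#' each category gets `floor(n * p)` and the leftover units go to the largest
#' fractional remainders (ties broken by category order).
#'
#' @param n Integer total to allocate.
#' @param p Numeric vector of non-negative fractions summing to 1.
#' @return Integer vector of counts summing to `n`, named like `p`.
#' @keywords internal
largestRemainder <- function(n, p) {
  stopifnot(length(n) == 1L, n >= 0)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("proportions must be non-negative and sum to 1")
  raw <- n * p
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[idx] <- counts[idx] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483562) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
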