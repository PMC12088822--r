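#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-stage substream: stable under stage reordering because each
# stage name hashes independently of the others.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

#' Half-up rounding
#'
#' Rounds to the printed precision of a report table with ties going away
#' from zero (base `round()` uses banker's rounding, which would make
#' comparisons against printed tables ill-defined).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max subtraction for numerical stability.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == floor(x) && x >= 0

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1
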