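#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded operations do not
#' clobber the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a child seed from a base seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 7919) %% 2147483587)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## pairwise Euclidean distance matrix for small n
pair_dist <- function(xy) {
  as.matrix(stats::dist(xy))
}
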