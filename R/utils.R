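# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded package functions never clobber a user's
#' random stream.  A `NULL` seed evaluates `expr` with the current stream.
#'
#' @param seed Integer scalar or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Draw n derived sub-seeds from the current RNG stream.  Components seeded
# from distinct sub-seeds are individually reproducible.
draw_subseeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Frobenius norm of a matrix.
fnorm <- function(m) sqrt(sum(m * m))

`%||%` <- function(x, y) if (is.null(x)) y else x
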