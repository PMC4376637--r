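# Internal numerical helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All package randomness flows through this so that no exported function
# clobbers the global stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Overflow-safe logistic; plogis is already safe but centralizing the call
# documents the constraint (k*|C - p| can exceed 700 in optimizer probes).
#' @keywords internal
sigmoid <- function(x) stats::plogis(x)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
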