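# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Evaluate code with a fixed RNG seed, restoring the caller's stream
#'
#' All randomized operations in the package route their draws through this
#' helper so that a given seed yields bit-identical output regardless of the
#' surrounding RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  code
}

# Derive a sub-seed from a base seed and a stream label, staying < 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 2003L + (as.integer(stream) %% 1000L)
}
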