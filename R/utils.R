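#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so generators are deterministic without clobbering
#' the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 7919) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
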