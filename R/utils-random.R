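#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so library code never clobbers user RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

#' Derive a deterministic substream seed from a master seed and indices
#'
#' Splitmix-style integer mixing so that each (sample, drug, concentration,
#' replicate) well gets its own reproducible stream derived from one master
#' seed. Result is always in [0, 2^31 - 2].
#'
#' @param seed master integer seed.
#' @param ... index values (integers or strings) identifying the substream.
#' @return a single integer seed.
#' @export
substream_seed <- function(seed, ...) {
  parts <- list(...)
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    }
    p <- as.numeric(p)
    if (!is.finite(p)) stop("substream index must be finite", call. = FALSE)
    # 64-bit-safe multiplicative mix kept inside double precision
    h <- (h * 48271 + abs(p) * 16807 + 12345) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h %% 2147483646)
}
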