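#' Derive a child seed from a master seed and a key path
#'
#' All stochastic operations in the package draw their randomness from child
#' seeds derived deterministically from a single integer master seed and a
#' sequence of string/integer keys (e.g. list id, pair id, purpose). This
#' replaces ad-hoc seeding (such as clock-based list selection) with a fully
#' reproducible scheme: the same master seed and key path always yield the
#' same child seed, and different key paths decorrelate.
#'
#' The derivation is a 31-bit multiplicative string hash over the decimal
#' rendering of each key, kept below 2^31 so it is always a valid R seed.
#'
#' @param master integer master seed.
#' @param ... keys (coerced to character) identifying the consumer.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "lists", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.double(master)) %% m
  keys <- vapply(list(...), function(k) paste(as.character(k), collapse = ","),
                 character(1))
  for (k in keys) {
    for (ch in utf8ToInt(k)) h <- (h * 31 + ch) %% m
    h <- (h * 31 + 7) %% m
  }
  as.integer(h)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state, so seeded package operations never disturb the global random
#' stream. A `NULL` seed evaluates the code under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
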