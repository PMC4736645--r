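#' Create a seeded random stream
#'
#' All stochastic draws of a simulation come from a single xoshiro256++
#' stream, so a run is fully determined by its seed: identical seed,
#' parameters and package version give a bit-identical trajectory. The
#' stream is stateful: every draw advances it in place.
#'
#' @param seed Non-negative integer seed.
#' @return An object of class `rng_stream`.
#' @examples
#' rng <- rng_stream(42)
#' rng_uniform(rng, 3)
#' @export
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) || seed < 0)
    stop("`seed` must be a single non-negative number", call. = FALSE)
  obj <- list(ptr = rng_create_(as.numeric(seed)), seed = as.numeric(seed))
  class(obj) <- "rng_stream"
  obj
}

#' Draw uniform variates from a random stream
#'
#' @param rng An [rng_stream()].
#' @param n Number of draws.
#' @return Numeric vector of `n` values uniform on `[0, 1)`.
#' @export
rng_uniform <- function(rng, n = 1) {
  stopifnot(inherits(rng, "rng_stream"))
  rng_unif_(rng$ptr, as.integer(n))
}

#' Save or restore the internal state of a random stream
#'
#' The state is returned as four hexadecimal words, suitable for inclusion in
#' plain-text snapshots so that an interrupted run can be resumed on the very
#' same stream position.
#'
#' @param rng An [rng_stream()].
#' @param state Character vector of four hexadecimal words as returned by
#'   `rng_state()`.
#' @return `rng_state()` returns a character vector of length 4;
#'   `rng_restore()` returns the stream, invisibly.
#' @export
rng_state <- function(rng) {
  stopifnot(inherits(rng, "rng_stream"))
  rng_get_state_(rng$ptr)
}

#' @rdname rng_state
#' @export
rng_restore <- function(rng, state) {
  stopifnot(inherits(rng, "rng_stream"))
  rng_set_state_(rng$ptr, as.character(state))
  invisible(rng)
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream> xoshiro256++, seed", format(x$seed), "\n")
  invisible(x)
}
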