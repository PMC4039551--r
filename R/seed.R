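#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hash used to give every replicate (and every cell of
#' a Monte Carlo table) its own RNG substream, so that any single replicate
#' can be regenerated in isolation and serial or re-ordered execution gives
#' identical results.
#'
#' @param master Master seed (integer-valued, < 2^31).
#' @param i Substream index (non-negative integer).
#' @return A positive integer seed below 2^31, suitable for [set.seed()].
#' @examples
#' substream_seed(42, 1)
#' @export
substream_seed <- function(master, i) {
  # affine hash mod the Mersenne prime 2^31 - 1; exact in double precision
  s <- (abs(as.double(master)) %% 2147483647) * 48271 + as.double(i) * 16807
  as.integer(s %% 2147483647 + 1)
}
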