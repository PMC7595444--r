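#' Derive a child seed from a stream of integer identifiers
#'
#' Hierarchical seeding for the simulation pipeline: a master seed is mixed
#' with per-model, per-replicate and per-stream identifiers to yield
#' independent, reproducible RNG streams. The mix is a multiplicative hash
#' over the identifiers, carried out in double precision (exact below 2^53)
#' and reduced modulo 2^31 - 1 so the result is always a valid 32-bit seed.
#'
#' @param ... Integer-valued identifiers, mixed left to right. The first is
#'   conventionally the master seed.
#' @return A single integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' mix_seed(1, 3, 7)
#' mix_seed(1, 3, 8) # a different stream
#' @export
mix_seed <- function(...) {
  ids <- c(...)
  stopifnot(length(ids) >= 1, all(is.finite(ids)))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in ids) {
    h <- (h * 48271 + (k %% m) + 11) %% m
  }
  as.integer(h)
}
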