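#' Deterministic seed splitting
#'
#' All generators draw their randomness from a single integer seed. Objects
#' generated inside a larger run (one spectrum class, one image, one
#' topography) each get their own sub-stream seed via a fixed linear
#' congruential hash of `(seed, index)`, so adding or reordering other
#' objects never perturbs an existing one and every result is reproducible
#' from the top-level seed alone.
#'
#' @param seed top-level integer seed
#' @param index non-negative integer identifying the sub-stream
#' @return an integer seed in [0, 2^31 - 1)
#' @export
sub_seed <- function(seed, index) {
  stopifnot(length(seed) == 1L, length(index) == 1L)
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 1299721 + 12345
  as.integer(s %% m)
}
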