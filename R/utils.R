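#' Derive a reproducible child seed from a master seed
#'
#' Counter-based fan-out: a master seed plus any number of integer stream
#' labels (width index, start id, iteration, candidate, rollout, ...) is
#' hashed to a seed in `[1, 2^31 - 2]` with a Lehmer-style mixing chain.
#' Exact in double arithmetic (products stay below 2^53), so the same
#' labels always yield the same stream regardless of platform.
#'
#' @param seed master seed (integer).
#' @param ... integer stream labels.
#' @return integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (x in c(...)) {
    h <- (h * 48271 + as.numeric(x) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
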