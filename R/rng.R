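#' Derive a reproducible child seed from a root seed and a label
#'
#' Each stochastic component of the simulator draws from its own stream,
#' seeded by hashing a fixed text label together with the root seed. Adding
#' a new component (with a new label) therefore never perturbs the draws of
#' existing components.
#'
#' @param seed integer root seed.
#' @param label character stream label, e.g. `"genotypes"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, keeps products exact in doubles
  h <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 69069 + code) %% m
  }
  as.integer(h)
}
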