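# One integer seed drives every stochastic stage.  Each stage draws from
# its own named substream so that adding or re-running one stage never
# perturbs the draws of another, and so that a dataset is bit-reproducible
# from (config, seed) alone.

#' Derive a substream seed from a master seed and a stream name
#'
#' Deterministically maps a (seed, name) pair to an integer in
#' `[0, 2^31)` suitable for [set.seed()].  Used internally by all
#' generator stages; exposed so that scripts can draw reproducible
#' per-task seeds from one command-line seed.
#'
#' @param seed Master integer seed.
#' @param name Character stream name (e.g. `"state-sequence"`).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629)
}
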