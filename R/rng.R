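## Seeded substreams: every stochastic ingredient (mirror jitter, drift,
## feedback noise, clock phase, photon noise, ...) draws from its own
## substream derived from the single run seed, so switching one noise source
## on or off never perturbs the draws of the others.

#' Derive a named substream seed from a run seed
#'
#' Combines an integer run seed with a stream name into a new 31-bit seed via
#' a multiplicative string hash.  Distinct names give (with overwhelming
#' probability) distinct, uncorrelated-in-practice seeds; the same
#' (seed, name) pair always maps to the same substream seed.
#'
#' @param seed integer run seed.
#' @param stream character scalar naming the noise source.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  ## golden-ratio style mixing of the run seed, then fold in the name hash
  s <- (as.numeric(seed) %% m) * 2654435761 %% m
  as.integer((s + h * 97 + 1) %% m)
}

## Evaluate `code` under a temporary RNG state seeded from (seed, stream),
## restoring the caller's .Random.seed afterwards.
with_substream <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}
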