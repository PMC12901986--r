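#' Derive a deterministic substream seed
#'
#' All stochastic operations in the package take an integer `seed` and, where
#' they need several independent random streams, derive per-stage seeds with
#' this helper so that a single global seed drives an entire pipeline run.
#' The derivation is a small multiplicative hash kept strictly below 2^31 so
#' the result is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param name character scalar naming the substream (e.g. `"fragments"`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- (abs(seed) %% 2147483647) + 1
  for (b in utf8ToInt(name)) h <- (h * 69069 + b * 2654435761) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
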