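# Reproducibility helpers: one master seed, deterministic substreams keyed by
# integer tags (participant, condition, iteration, ...), so any block of the
# simulation can be regenerated in isolation and in any order.

#' Derive a deterministic substream seed from a master seed and integer keys
#'
#' Folds the master seed and any number of integer keys into a single seed in
#' `[1, 2^31 - 2]` with a multiplicative hash. The map is deterministic and
#' spreads neighbouring keys far apart, so streams keyed by, say,
#' `(participant, iteration)` are effectively independent.
#'
#' @param master Master seed (integer-valued scalar).
#' @param ... Integer-valued keys identifying the substream.
#' @return A single integer seed suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, 7, 3) != substream_seed(1, 3, 7)
substream_seed <- function(master, ...) {
  keys <- c(master, ...)
  if (!length(keys) || !all(is.finite(keys))) {
    stop("substream_seed() needs finite numeric keys")
  }
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in as.numeric(keys)) {
    h <- (h * 48271 + (k %% m) + 11) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards (or removed if there was none).
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
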