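# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All user-facing randomised operations route through
# this so a single integer seed makes them reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Derive a component seed from a global seed
#'
#' Fans one global seed out to per-component seeds through a fixed string hash,
#' so that a single `--seed` controls every source of randomness in a run
#' while components stay decoupled.
#'
#' @param seed Integer global seed.
#' @param component Character name of the component.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
seed_fanout <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  h <- 0
  for (v in utf8ToInt(component)) h <- (h * 31 + v) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
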