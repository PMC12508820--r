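# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so library code never clobbers
#' the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Derive a stable child seed from a parent seed and a stream label
#'
#' Deterministic integer mixing (multiplicative congruential over the
#' Mersenne prime 2^31 - 1) so each stage / session / fold gets an
#' independent, reproducible stream. Keeps every derived seed in
#' [1, 2^31 - 2].
#' @noRd
mix_seed <- function(...) {
  parts <- list(...)
  h <- 104729
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.numeric(p)) {
      h <- (h * 48271 + abs(v) + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483645) + 1L
}

#' Cheap FNV-style hash of a config for provenance records
#' @noRd
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
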