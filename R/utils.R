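#' Derive a named RNG stream seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its randomness from its own
#' stream, derived deterministically from a single master seed and the stage
#' name. The derivation is `(master * 7919 + hash(stage)) mod (2^31 - 1)`,
#' where `hash` sums the UTF-8 code points of the stage name weighted by
#' position. Any single stage (or cross-validation round) can therefore be
#' re-run in isolation from the master seed alone.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"genotypes"`, `"round_17"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp)) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Run code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Small assertion helper with sprintf-style messages.
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
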