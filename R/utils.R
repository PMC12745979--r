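# Small shared helpers.

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards. All package randomness flows through
#' this, which is what makes every pipeline stage independently
#' reproducible.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Gives every experiment component (per-sequence sampling, per-repeat
#' randomization, ...) its own deterministic stream from one top-level
#' seed. The result stays inside the 32-bit integer range.
#'
#' @param seed integer parent seed.
#' @param label character (or coercible) stream label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
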