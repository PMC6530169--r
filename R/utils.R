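# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Display rounding for the evaluation tables. Base round() (round half
# to even at exact decimal midpoints, e.g. 0.745 -> 0.74) reproduces the
# published tables; strict half-up does not (it would print 0.75 there).
display_round <- function(x, digits = 2L) {
  round(x, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
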