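# Classed conditions so callers (and the CLI) can distinguish bad input from
# I/O failure.  Exit-code contract downstream: validation -> 1, I/O -> 2.

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("organoidscreen_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_io <- function(msg, ...) {
  stop(structure(
    class = c("organoidscreen_io_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  All stochastic code in the package funnels
# through this, so a seed fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed %% .Machine$integer.max)
  }
  force(expr)
}
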