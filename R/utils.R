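# Seed handling: set a local RNG state and restore the caller's afterwards,
# so package functions are reproducible from their `seed` arguments without
# disturbing the global stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Child seeds derived reproducibly from a parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  sample.int(.Machine$integer.max, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-8 guards against binary representation of decimal halves
  # (e.g. 1.005 * 100 = 100.4999...) being floored the wrong way
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}
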