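`%||%` <- function(a, b) if (is.null(a)) b else a

# round a raw slider increment to 1 or 2 significant figures, keeping it
# a "presentable" step (1, 2, 2.5 or 5 times a power of ten)
nice_step <- function(raw) {
  stopifnot(is.finite(raw), raw > 0)
  mag <- 10^floor(log10(raw))
  frac <- raw / mag
  step <- if (frac < 1.5) 1 else if (frac < 2.25) 2 else if (frac < 3.5) 2.5 else if (frac < 7.5) 5 else 10
  step * mag
}

# run an expression with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
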