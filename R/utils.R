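# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring any prior RNG state on exit
# so that simulators never leak global state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.assertProportion <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, what, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(what, " must be an integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

.assertPositive <- function(x, what, strict = TRUE) {
  if (any(!is.finite(x)) || (strict && any(x <= 0)) || (!strict && any(x < 0)))
    stop(what, " must be ", if (strict) "> 0" else ">= 0", call. = FALSE)
  invisible(x)
}
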