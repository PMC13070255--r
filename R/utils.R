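# Small internal utilities.

# Run `expr` under a locally seeded RNG without disturbing global RNG state.
# Every generator routes its draws through this, so a fixed seed gives
# bit-identical output regardless of what the caller has done with set.seed().
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop(sprintf("`%s` must be a %s finite scalar", name,
                        if (strict) "positive" else "non-negative"),
                call. = FALSE)
  invisible(x)
}
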