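# internal helpers

# Run expr under a fixed seed (when non-NULL), restoring the caller's RNG
# state afterwards so library code never disturbs the session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stage seed from a global seed; stays below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("`%s` must be a %s finite scalar", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}
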