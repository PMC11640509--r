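`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

assert_count <- function(x, name, min = 1L) {
  if (!is_count(x, min)) stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min)
    stopf("`%s` must be a single finite number >= %s", name, format(min))
  as.numeric(x)
}
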