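# Internal validation helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         finite = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_bad(sprintf("'%s' must be a single number", name))
  if (finite && !is.finite(x))
    stop_bad(sprintf("'%s' must be finite", name))
  if (x < lower || x > upper)
    stop_bad(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  if (integer && x != round(x))
    stop_bad(sprintf("'%s' must be an integer, got %s", name, x))
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_bad(sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

# Deterministic per-unit seed derivation: a fixed odd multiplier keeps
# distinct counters on distinct streams while staying below 2^31.
derive_seed <- function(master, counter) {
  (as.double(master) * 48271 + as.double(counter) * 7919) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
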