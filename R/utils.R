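# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a master seed and a sequence of
# keys (integers or strings). Keeps every derived seed in [0, 2^31 - 2] so it
# is always a valid argument to set.seed().
derive_seed <- function(seed, ...) {
  keys <- list(...)
  s <- as.double(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k))
    s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

# Run code under a temporary RNG state; restores the caller's stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
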