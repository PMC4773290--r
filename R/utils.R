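# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# log(sum(exp(x))) without overflow; -Inf for empty/all -Inf input.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf (with warning) when numerical
# noise gives a < b, so callers can clamp instead of producing NaN.
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (a < b) {
    warning("log-difference of a negative quantity; clamping to -Inf")
    return(-Inf)
  }
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
warn2 <- function(...) warning(sprintf(...), call. = FALSE)
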