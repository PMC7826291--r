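# Internal numeric helpers shared across modules.

# Elementwise log(exp(a) + exp(b)), safe for -Inf (empty terms) on either side.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  bad <- is.infinite(m)
  out[bad] <- m[bad]
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (strict && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  invisible(x)
}

# clamp to [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
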