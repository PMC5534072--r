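# internal helpers shared across modules

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; a NULL seed means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# stop() with the calling function's name stripped from the message
fail <- function(...) stop(..., call. = FALSE)

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    fail(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)))
  }
  invisible(x)
}

# row-wise population standard deviation (denominator n)
rowSdPop <- function(x) {
  m <- rowMeans(x)
  sqrt(rowMeans((x - m)^2))
}
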