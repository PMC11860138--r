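# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside the supported range %s%g, %g%s", name, x,
          if (allow_equal_lower) "[" else "(", lower, upper,
          if (allow_equal_upper) "]" else ")")
  invisible(x)
}

# derive a child seed from the current RNG stream, staying below 2^31
derive_seed <- function() sample.int(.Machine$integer.max, 1L)
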