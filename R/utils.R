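# Internal argument checks shared across modules.

check_numeric_series <- function(x, arg = "x", min_len = 1L) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric vector.", arg))
  }
  if (length(x) < min_len) {
    abort(sprintf("`%s` must have at least %d samples.", arg, min_len))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(x)
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf,
                         integerish = FALSE, strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper &&
    (!integerish || x == round(x))
  if (!ok) {
    abort(sprintf("`%s` must be a single %s in %s%s, %s].",
                  arg, if (integerish) "integer" else "number",
                  if (strict_lower) "(" else "[",
                  format(lower), format(upper)))
  }
  invisible(x)
}

check_flag <- function(x, arg) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", arg))
  }
  invisible(x)
}

# Derive a 32-bit-safe child seed from a master seed and a stream index.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %%
               2147483629)
}
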