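# Internal helpers shared across modules.

# Derive a vector of child seeds from a master seed without touching the
# caller's RNG state. Seeds stay below 2^31 - 1.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, n))
}

# Stop with a formatted message.
stopf <- function(fmt, ...) {
  abort(sprintf(fmt, ...))
}

check_range <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    stopf("`%s` must be numeric in [%s, %s].", name, format(lo), format(hi))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be TRUE or FALSE.", name)
  }
  invisible(x)
}

# Column-presence assertion for data-frame-first functions.
check_cols <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stopf("%s(): `data` is missing column(s): %s.", fn,
          paste(missing, collapse = ", "))
  }
  invisible(data)
}
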