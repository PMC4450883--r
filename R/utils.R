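# Internal helpers shared across modules.

# Clamp integer indices into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stop with a consistent message when `ok` is false.
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Coerce a point to a length-2 numeric (row, col) vector.
as_point <- function(point) {
  p <- as.numeric(point)
  assert_that(length(p) == 2L && all(is.finite(p)),
              "a point must be a finite (row, col) pair")
  p
}

# Derive `n` reproducible sub-seeds from a master seed without disturbing
# the caller's RNG state. Kept below 2^31 so they are valid R integers.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

point_in_bounds <- function(p, shape) {
  p[1] >= 1 && p[1] <= shape[1] && p[2] >= 1 && p[2] <= shape[2]
}
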