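# Shared fixtures: small frames and randomized SVM models built in code.

# A quiet phantom suitable for fast tests (no jitter surprises at 64 px).
test_params <- function(...) {
  phantom_params(image_height = 96L, image_width = 96L, jitter_px = 3L, ...)
}

# Constant-intensity frame.
const_frame <- function(value = 100, h = 64L, w = 64L, spacing = 1) {
  gray_frame(matrix(value, h, w), pixel_spacing_mm = spacing)
}

# Random intersection-kernel model with the documented field layout;
# coefficients and bias are arbitrary reals, support values in [0, 255].
rand_ik_model <- function(m, n, tie_fraction = 0) {
  sv <- matrix(runif(m * n, 0, 255), m, n)
  if (tie_fraction > 0 && m > 1) {
    k <- ceiling(length(sv) * tie_fraction)
    idx <- sample(length(sv), k)
    sv[idx] <- round(sv[idx] / 10) * 10   # coarse grid forces duplicates
  }
  structure(list(sv = sv, coef = runif(m, -1, 1), b = runif(1, -2, 2),
                 C = 1, kernel = "intersection", sigma = NULL, dim = n,
                 layout = NULL),
            class = "iksvm_model")
}

# A model that rejects every query: zero coefficients, large negative bias.
always_negative_model <- function(n) {
  structure(list(sv = matrix(1, 1L, n), coef = 0, b = -1e6, C = 1,
                 kernel = "intersection", sigma = NULL, dim = n,
                 layout = NULL),
            class = "iksvm_model")
}

# Candidate set wrapper around a bare point matrix.
as_candidates <- function(points, shape) {
  structure(data.frame(row = points[, 1], col = points[, 2],
                       decision = rep(1, nrow(points))),
            class = c("candidate_set", "data.frame"),
            frame_id = "fixture", shape = shape, stride = 1L)
}

# Brute-force density field: double loop over (pixel, candidate) pairs.
brute_density <- function(points, shape, R) {
  vals <- matrix(0, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (cl in seq_len(shape[2])) {
    for (k in seq_len(nrow(points))) {
      d <- abs(points[k, 1] - r) + abs(points[k, 2] - cl)
      if (d < R) vals[r, cl] <- vals[r, cl] + (R - d)
    }
  }
  vals
}

# Deterministic per-frame localization errors (px) for a set of frames.
pixel_errors <- function(results, frames) {
  t(vapply(seq_along(frames), function(k) {
    r <- results[[k]]; tr <- frames[[k]]$truth
    if (!isTRUE(r$detected)) return(c(septal = NA_real_, lateral = NA_real_))
    c(septal = sqrt(sum((r$septal - tr["septal", ])^2)),
      lateral = sqrt(sum((r$lateral - tr["lateral", ])^2)))
  }, numeric(2)))
}
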