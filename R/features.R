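#' Sampling pattern of the sparse local-context feature
#'
#' The local-context feature of a pixel is built from mean-filtered gray
#' values sampled along eight directions at 45-degree intervals, at a fixed
#' set of radii, plus (optionally) the centre pixel. Sampling is sparse and
#' densest near the centre, where the context carries the most information
#' about the pixel; the default radii reach out to 29 px, matching the
#' scale of cardiac structures in a four-chamber view.
#'
#' The feature layout is frozen: the centre value first (when included),
#' then directions in the fixed order
#' `(0,1), (1,1), (1,0), (1,-1), (0,-1), (-1,-1), (-1,0), (-1,1)`
#' (row, col offsets, rows increasing downward), radii ascending within
#' each direction. With the defaults the feature has
#' `8 * 8 + 1 = 65` dimensions.
#'
#' @param radii Strictly increasing positive integer sampling distances.
#' @param include_center Include the centre pixel's value as the first
#'   entry.
#' @param window Odd side length of the mean filter applied at every
#'   sampling point (`1` disables smoothing).
#' @return An object of class `sampling_pattern`.
#' @export
sampling_pattern <- function(radii = c(1L, 3L, 5L, 9L, 13L, 17L, 23L, 29L),
                             include_center = TRUE, window = 3L) {
  radii <- as.integer(radii)
  assert_that(length(radii) >= 1L && all(radii > 0L) &&
                all(diff(radii) > 0L),
              "radii must be strictly increasing positive integers")
  window <- as.integer(window)
  assert_that(window >= 1L && window %% 2L == 1L,
              "window must be a positive odd integer")
  directions <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                      c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  storage.mode(directions) <- "integer"
  colnames(directions) <- c("row", "col")
  structure(list(radii = radii, directions = directions,
                 include_center = isTRUE(include_center), window = window),
            class = "sampling_pattern")
}

#' Feature dimension of a sampling pattern
#' @param pattern A [sampling_pattern()].
#' @return Integer: `|directions| * |radii| + include_center`.
#' @export
feature_length <- function(pattern) {
  nrow(pattern$directions) * length(pattern$radii) +
    as.integer(pattern$include_center)
}

# Short fingerprint tying a trained model to the feature layout it expects.
pattern_fingerprint <- function(pattern) {
  sprintf("r=%s;c=%d;w=%d", paste(pattern$radii, collapse = ","),
          as.integer(pattern$include_center), pattern$window)
}

# (row, col) offsets of all sampling points, in the frozen layout order.
pattern_offsets <- function(pattern) {
  per_dir <- lapply(seq_len(nrow(pattern$directions)), function(d) {
    cbind(pattern$directions[d, 1] * pattern$radii,
          pattern$directions[d, 2] * pattern$radii)
  })
  off <- do.call(rbind, per_dir)
  if (pattern$include_center) off <- rbind(c(0L, 0L), off)
  off
}

# Replicate-edge padding: value at any out-of-range index equals the
# nearest edge pixel.
pad_replicate <- function(px, pad) {
  px[clamp(seq(1L - pad, nrow(px) + pad), 1L, nrow(px)),
     clamp(seq(1L - pad, ncol(px) + pad), 1L, ncol(px)), drop = FALSE]
}

# Box mean filter by summing shifted submatrices; returns a matrix smaller
# than the input by (window - 1) on each axis.
box_mean <- function(px, window) {
  if (window == 1L) return(px)
  half <- (window - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0, nr - 2L * half, nc - 2L * half)
  for (dr in -half:half) for (dc in -half:half) {
    out <- out + px[(1L + half + dr):(nr - half + dr),
                    (1L + half + dc):(nc - half + dc)]
  }
  out / (window * window)
}

#' Mean-filtered sample at a pixel
#'
#' Arithmetic mean of the `window` x `window` neighbourhood of `point`
#' under replicate-edge padding. This is the per-sampling-point smoothing
#' that makes the local-context feature robust to speckle: a raw gray value
#' in heavy multiplicative noise is unreliable, while a small (3x3) mean
#' still reflects the local tissue intensity without blurring structure.
#'
#' @param frame A [gray_frame()] (or bare numeric matrix).
#' @param point `(row, col)` coordinate, 1-based, inside the image.
#' @param window Odd window size.
#' @return The neighbourhood mean, a scalar in `[0, 255]`.
#' @export
mean_sample <- function(frame, point, window = 3L) {
  px <- if (inherits(frame, "gray_frame")) frame$pixels else frame
  p <- as_point(point)
  assert_that(point_in_bounds(p, dim(px)),
              "sampling point lies outside the image")
  window <- as.integer(window)
  assert_that(window >= 1L && window %% 2L == 1L,
              "window must be a positive odd integer")
  half <- (window - 1L) %/% 2L
  rows <- clamp(p[1] + (-half:half), 1L, nrow(px))
  cols <- clamp(p[2] + (-half:half), 1L, ncol(px))
  mean(px[rows, cols])
}

#' Extract local-context features for a batch of pixels
#'
#' Vectorised form of [extract_feature()]: the frame is smoothed once and
#' each point's feature is gathered by indexing, so scanning a whole frame
#' costs one pass of the mean filter plus O(points x dimensions) lookups.
#'
#' @param frame A [gray_frame()] (or bare numeric matrix).
#' @param points Integer matrix with one `(row, col)` point per row.
#' @param pattern A [sampling_pattern()].
#' @param border If `TRUE` (default), sampling offsets falling outside the
#'   image use replicate-edge padding; if `FALSE`, every point must be at
#'   least `max(radii)` away from the border.
#' @return Numeric matrix, one feature row per point, `feature_length(pattern)`
#'   columns.
#' @export
extract_features_batch <- function(frame, points, pattern = sampling_pattern(),
                                   border = TRUE) {
  px <- if (inherits(frame, "gray_frame")) frame$pixels else frame
  points <- matrix(as.integer(points), ncol = 2L)
  d <- feature_length(pattern)
  if (nrow(points) == 0L)
    return(matrix(numeric(0), 0L, d))
  assert_that(all(points[, 1] >= 1L & points[, 1] <= nrow(px) &
                    points[, 2] >= 1L & points[, 2] <= ncol(px)),
              "all points must lie inside the image")
  maxr <- max(pattern$radii)
  assert_that(maxr <= min(dim(px)) %/% 2L,
              "max sampling radius exceeds half the image size")
  if (!border) {
    ok <- points[, 1] > maxr & points[, 1] <= nrow(px) - maxr &
      points[, 2] > maxr & points[, 2] <= ncol(px) - maxr
    assert_that(all(ok), sprintf(
      "point %d is within max(radii) of the border and border policy is off",
      which(!ok)[1]))
  }
  half <- (pattern$window - 1L) %/% 2L
  padded <- pad_replicate(px, maxr + half)
  # smoothed values for all image coordinates in [1-maxr, dim+maxr]
  sm <- box_mean(padded, pattern$window)
  off <- pattern_offsets(pattern)
  ridx <- outer(points[, 1], off[, 1], `+`) + maxr   # n x d
  cidx <- outer(points[, 2], off[, 2], `+`) + maxr
  vals <- sm[cbind(as.vector(ridx), as.vector(cidx))]
  matrix(vals, nrow(points), d)
}

#' Extract the sparse local-context feature at one pixel
#'
#' Returns the mean-filtered gray values at the centre (optional) and at
#' each `(direction, radius)` sampling offset, in the frozen layout
#' documented in [sampling_pattern()]. Values are raw gray means in
#' `[0, 255]` — nonnegative, as the histogram intersection kernel requires —
#' not normalised histograms.
#'
#' @inheritParams extract_features_batch
#' @param point `(row, col)` coordinate, 1-based.
#' @return Numeric vector of length `feature_length(pattern)`.
#' @examples
#' fr <- generate_frame(phantom_params(speckle_shape = Inf))
#' length(extract_feature(fr, c(64, 64)))  # 65 with the defaults
#' @export
extract_feature <- function(frame, point, pattern = sampling_pattern(),
                            border = TRUE) {
  p <- as_point(point)
  drop(extract_features_batch(frame, matrix(p, 1L), pattern, border))
}

#' Write a feature matrix with point metadata to CSV
#'
#' One row per point: `frame_id, row, col, label, v1..vD`. Used to persist
#' training sets for reproducible model fits.
#'
#' @param features Numeric feature matrix (points x dimensions).
#' @param meta Data frame with columns `frame_id`, `row`, `col`, `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, meta, path) {
  assert_that(nrow(features) == nrow(meta),
              "features and meta must have the same number of rows")
  colnames(features) <- sprintf("v%d", seq_len(ncol(features)))
  utils::write.csv(cbind(meta, features), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_features()]
#' @param path CSV path.
#' @return List with `features` (matrix), `labels` (numeric +-1) and `meta`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df))
  list(features = as.matrix(df[, vcols]),
       labels = df$label,
       meta = df[, c("frame_id", "row", "col", "label")])
}
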