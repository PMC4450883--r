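#' Block (Manhattan, L1) distance between pixel coordinates
#'
#' @param p,q `(row, col)` coordinate pairs.
#' @return `|dr| + |dc|`, a nonnegative number.
#' @export
block_distance <- function(p, q) {
  p <- as_point(p); q <- as_point(q)
  sum(abs(p - q))
}

#' Weighted density field of a candidate set
#'
#' Each SVM-positive candidate stamps a diamond-shaped weight template on
#' the field: a pixel `A` accumulates `R - D_block(y, A)` from every
#' candidate `y` within block distance `< R`. True hinge candidates form
#' dense clusters and light up; scattered false positives stay dim, so the
#' field separates the two regimes. The default radius `R = 10` matches
#' the weighted-template size tuned for the mitral annulus scale; `R = 8`
#' behaves nearly identically.
#'
#' @param candidates A `candidate_set` (or data frame / 2-column matrix of
#'   `(row, col)` points).
#' @param shape `c(rows, cols)` of the field; defaults to the candidate
#'   set's frame shape.
#' @param R Template radius (the weight at block distance 0).
#' @return An object of class `density_field`: list with `values` (matrix
#'   of nonnegative weights, zero wherever no candidate is within block
#'   distance `< R`) and `R`.
#' @export
density_field <- function(candidates, shape = attr(candidates, "shape"),
                          R = 10L) {
  pts <- candidate_points(candidates)
  R <- as.integer(R)
  assert_that(R >= 1L, "template radius R must be >= 1")
  assert_that(length(shape) == 2L && all(shape >= 1),
              "shape must be c(rows, cols)")
  vals <- matrix(0, shape[1], shape[2])
  if (nrow(pts) > 0) {
    assert_that(all(pts[, 1] >= 1 & pts[, 1] <= shape[1] &
                      pts[, 2] >= 1 & pts[, 2] <= shape[2]),
                "candidate outside the field shape")
    # diamond template: weight R - (|dr| + |dc|) where positive
    span <- -(R - 1L):(R - 1L)
    tmpl <- pmax(R - outer(abs(span), abs(span), `+`), 0)
    for (k in seq_len(nrow(pts))) {
      r0 <- pts[k, 1]; c0 <- pts[k, 2]
      rr <- max(1L, r0 - R + 1L):min(shape[1], r0 + R - 1L)
      cc <- max(1L, c0 - R + 1L):min(shape[2], c0 + R - 1L)
      vals[rr, cc] <- vals[rr, cc] + tmpl[rr - r0 + R, cc - c0 + R]
    }
  }
  structure(list(values = vals, R = R), class = "density_field")
}

# Accept candidate_set / data frame / matrix and return an integer matrix
# of (row, col) points.
candidate_points <- function(candidates) {
  if (is.data.frame(candidates)) {
    m <- cbind(candidates$row, candidates$col)
  } else {
    m <- as.matrix(candidates)
  }
  if (length(m) == 0L) return(matrix(integer(0), 0L, 2L))
  matrix(as.integer(round(m)), ncol = 2L)
}

#' Label connected components of a binary mask
#'
#' Breadth-first labelling with 4- or 8-connectivity. Small utility used by
#' the adaptive threshold; exported for testability.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_that(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  offs <- if (connectivity == 4L) cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
          else as.matrix(expand.grid(dr = -1L:1L, dc = -1L:1L))[-5L, ]
  todo <- which(mask)
  current <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    current <- current + 1L
    frontier <- start
    labels[start] <- current
    while (length(frontier) > 0L) {
      fr <- ((frontier - 1L) %% h) + 1L
      fc <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nr <- fr + offs[k, 1]; nc <- fc + offs[k, 2]
        ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
        if (!any(ok)) next
        lin <- (nc[ok] - 1L) * h + nr[ok]
        lin <- lin[mask[lin] & labels[lin] == 0L]
        if (length(lin) > 0L) {
          labels[lin] <- current
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

# Coordinates of each labelled component, ordered by label.
component_coords <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  lapply(ids, function(i) {
    w <- which(labels == i)
    cbind(row = ((w - 1L) %% nrow(labels)) + 1L,
          col = ((w - 1L) %/% nrow(labels)) + 1L)
  })
}

#' Adaptive threshold on the density field
#'
#' Searches for a threshold `H` such that the pixels with field value
#' strictly greater than `H` form exactly two connected components — the
#' two hinge-point clusters. The search is a binary search over the sorted
#' distinct field values: too few components means `H` is too high
#' (regions merged away), so `H` decreases; too many means `H` is too low,
#' so `H` increases. Because the component count is not monotone in `H`,
#' every probe is recorded; if no probe yields exactly two components the
#' search falls back to the probe with the most components and keeps the
#' two with the largest summed field weight, flagging the result.
#'
#' @param field A [density_field()].
#' @param connectivity 4 or 8 (component connectivity).
#' @return List with `threshold` (`min(field) <= H < max(field)`),
#'   `components` (list of coordinate matrices; two unless degenerate),
#'   `n_components`, `fallback` flag and the `probes` data frame.
#' @export
adaptive_threshold <- function(field, connectivity = 8L) {
  vals <- field$values
  assert_that(any(vals > 0),
              "refinement error: density field has no positive values")
  distinct <- sort(unique(vals[vals > 0]))
  maxv <- distinct[length(distinct)]
  # thresholds producing distinct masks: the field minimum (keeps all
  # positive pixels) and every distinct positive value below the maximum
  hs <- sort(unique(c(min(vals), distinct[distinct < maxv])))
  probes <- list()
  probe <- function(H) {
    labels <- label_components(vals > H, connectivity)
    comps <- component_coords(labels)
    probes[[length(probes) + 1L]] <<- list(H = H, count = length(comps),
                                           comps = comps)
    length(comps)
  }
  lo <- 1L; hi <- length(hs)
  found <- NULL
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    cnt <- probe(hs[mid])
    if (cnt == 2L) { found <- probes[[length(probes)]]; break }
    if (cnt < 2L) hi <- mid - 1L else lo <- mid + 1L
  }
  fallback <- is.null(found)
  if (fallback) {
    counts <- vapply(probes, `[[`, integer(1), "count")
    best <- probes[[which.max(counts)]]
    if (best$count > 2L) {
      weight <- vapply(best$comps, function(m) sum(vals[m]), numeric(1))
      best$comps <- best$comps[order(weight, decreasing = TRUE)[1:2]]
      best$count <- 2L
    }
    found <- best
  }
  list(threshold = found$H, components = found$comps,
       n_components = length(found$comps), fallback = fallback,
       probes = data.frame(
         H = vapply(probes, `[[`, numeric(1), "H"),
         n_components = vapply(probes, `[[`, integer(1), "count")))
}

#' Centroids of two components
#'
#' @param components List of two non-empty coordinate matrices.
#' @return 2x2 matrix of `(row, col)` centroids (coordinate means).
#' @export
component_centroids <- function(components) {
  assert_that(length(components) == 2L &&
                all(vapply(components, nrow, integer(1)) > 0L),
              "exactly two non-empty components required")
  t(vapply(components, colMeans, numeric(2)))
}

#' Two-centre K-means refinement of the candidate set
#'
#' The adaptive threshold can discard genuine hinge candidates along with
#' the noise, biasing the component centroids. To recover them, candidates
#' within block distance `scale` of either centroid are re-partitioned by
#' a two-cluster K-means seeded at the centroids (Euclidean assignment,
#' mean update, at most `max_iter` sweeps); the final cluster means,
#' rounded to the nearest pixel, are the hinge points. The septal point is
#' the leftmost (smaller column) by labelling convention.
#'
#' @param candidates Candidate set (or point matrix).
#' @param centers 2x2 matrix of distinct initial centres `(row, col)`.
#' @param scale Gating radius in pixels (block distance) around each
#'   initial centre; the mitral annulus has a roughly fixed physical size,
#'   so a fixed gate (default `2 * R` in [localize()]) suffices.
#' @param max_iter Iteration cap.
#' @return An object of class `hinge_result` with integer `septal` and
#'   `lateral` points, the final `centers`, the two `clusters` and a
#'   `reinitialized` flag (set when a cluster emptied and was reseeded at
#'   its initial centre).
#' @export
kmeans_refine <- function(candidates, centers, scale = 20, max_iter = 100L) {
  pts <- candidate_points(candidates)
  centers <- matrix(as.numeric(centers), 2L)
  assert_that(scale > 0, "scale must be positive")
  assert_that(any(centers[1, ] != centers[2, ]),
              "initial centres must be distinct")
  d_block <- function(m, ctr) abs(m[, 1] - ctr[1]) + abs(m[, 2] - ctr[2])
  keep <- d_block(pts, centers[1, ]) <= scale |
          d_block(pts, centers[2, ]) <= scale
  pts <- pts[keep, , drop = FALSE]
  assert_that(nrow(pts) > 0,
              "refinement error: no candidates within scale of the centres")
  init <- centers
  reinit <- FALSE
  assign_prev <- rep(0L, nrow(pts))
  for (it in seq_len(max_iter)) {
    d1 <- (pts[, 1] - centers[1, 1])^2 + (pts[, 2] - centers[1, 2])^2
    d2 <- (pts[, 1] - centers[2, 1])^2 + (pts[, 2] - centers[2, 2])^2
    assign <- ifelse(d1 <= d2, 1L, 2L)
    for (j in 1:2) {
      members <- pts[assign == j, , drop = FALSE]
      if (nrow(members) == 0L) {
        centers[j, ] <- init[j, ]   # reseed an emptied cluster
        reinit <- TRUE
      } else {
        centers[j, ] <- colMeans(members)
      }
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  hinge_result(centers, clusters = list(pts[assign == 1L, , drop = FALSE],
                                        pts[assign == 2L, , drop = FALSE]),
               reinitialized = reinit)
}

# Build a hinge_result from two cluster centres, enforcing the
# septal-is-leftmost labelling convention.
hinge_result <- function(centers, clusters = NULL, detected = TRUE, ...) {
  extras <- list(...)
  if (detected) {
    ord <- order(centers[, 2])
    centers <- centers[ord, , drop = FALSE]
    if (!is.null(clusters)) clusters <- clusters[ord]
    res <- list(detected = TRUE,
                septal = as.integer(round(centers[1, ])),
                lateral = as.integer(round(centers[2, ])),
                centers = centers, clusters = clusters)
  } else {
    res <- list(detected = FALSE, septal = NULL, lateral = NULL,
                centers = NULL, clusters = NULL)
  }
  structure(c(res, extras), class = "hinge_result")
}

#' @export
print.hinge_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<hinge_result: septal (%d, %d), lateral (%d, %d)%s>\n",
                x$septal[1], x$septal[2], x$lateral[1], x$lateral[2],
                if (isTRUE(x$fallback)) ", threshold fallback" else ""))
  } else {
    cat("<hinge_result: no detection>\n")
  }
  invisible(x)
}

#' Refinement-stage configuration
#'
#' @param stride Scan stride in pixels.
#' @param roi Optional scan rectangle `c(row_min, row_max, col_min,
#'   col_max)`.
#' @param R Density-field template radius.
#' @param connectivity Component connectivity (4 or 8).
#' @param scale K-means gating radius; defaults to `2 * R`.
#' @param use_fast Use the table-based SVM evaluation.
#' @return A list of class `refine_config`.
#' @export
refine_config <- function(stride = 1L, roi = NULL, R = 10L,
                          connectivity = 8L, scale = NULL, use_fast = TRUE) {
  structure(list(stride = as.integer(stride), roi = roi, R = as.integer(R),
                 connectivity = as.integer(connectivity),
                 scale = if (is.null(scale)) 2L * as.integer(R) else scale,
                 use_fast = isTRUE(use_fast)),
            class = "refine_config")
}

#' Locate the two hinge points in a frame
#'
#' Runs the full three-layer flow: pixel scan with the trained classifier,
#' weighted density field, adaptive threshold to exactly two components,
#' component centroids, and K-means refinement. Deterministic given its
#' inputs.
#'
#' @param frame A [gray_frame()].
#' @param model A trained `iksvm_model` (or `iksvm_tables`).
#' @param pattern The [sampling_pattern()] used in training.
#' @param config A [refine_config()].
#' @return A `hinge_result`. When no candidate survives, or the threshold
#'   stage cannot produce two distinct clusters, the result has
#'   `detected = FALSE` rather than raising an error; intermediate
#'   artifacts (`candidates`, `field`, `threshold`, `centroids`,
#'   `fallback`) are attached for inspection.
#' @export
localize <- function(frame, model, pattern = sampling_pattern(),
                     config = refine_config()) {
  cands <- scan_frame(frame, model, pattern, stride = config$stride,
                      roi = config$roi, use_fast = config$use_fast)
  if (nrow(cands) == 0L)
    return(hinge_result(NULL, detected = FALSE, candidates = cands,
                        reason = "empty candidate set"))
  field <- density_field(cands, dim(frame$pixels), R = config$R)
  thr <- adaptive_threshold(field, config$connectivity)
  if (thr$n_components < 2L)
    return(hinge_result(NULL, detected = FALSE, candidates = cands,
                        field = field, threshold = thr$threshold,
                        fallback = TRUE,
                        reason = "threshold stage found a single component"))
  cents <- component_centroids(thr$components)
  if (all(cents[1, ] == cents[2, ]))
    return(hinge_result(NULL, detected = FALSE, candidates = cands,
                        field = field, threshold = thr$threshold,
                        fallback = TRUE, reason = "coincident centroids"))
  res <- kmeans_refine(cands, cents, scale = config$scale)
  res$candidates <- cands
  res$field <- field
  res$threshold <- thr$threshold
  res$centroids <- cents
  res$fallback <- thr$fallback
  res$frame_id <- frame$frame_id
  res
}

#' Serialize a hinge result to JSON
#' @param result A `hinge_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hinge_result <- function(result, path) {
  obj <- list(frame_id = result$frame_id, detected = result$detected,
              septal = result$septal, lateral = result$lateral,
              threshold = result$threshold,
              fallback = isTRUE(result$fallback),
              reinitialized = isTRUE(result$reinitialized))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
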