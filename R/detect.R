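#' Training-set construction parameters
#'
#' Defines how labelled examples are sampled from annotated frames:
#' every pixel within `positive_radius` (Euclidean) of a ground-truth hinge
#' point is a positive; `negatives_per_frame` pixels at distance at least
#' `negative_min_distance` from both hinge points are drawn uniformly (on
#' the `stride` grid) as negatives. The gap between the two radii leaves
#' ambiguous near-hinge pixels unlabelled.
#'
#' @param positive_radius Pixels; label-positive zone around each truth
#'   point (0 keeps only the truth pixels themselves).
#' @param negative_min_distance Pixels; exclusion radius for negatives.
#'   Must exceed `positive_radius`.
#' @param negatives_per_frame Number of negatives sampled per frame.
#' @param stride Grid step for candidate negative locations.
#' @param seed Seed making the sampling reproducible.
#' @return An object of class `training_spec`.
#' @export
training_spec <- function(positive_radius = 2L, negative_min_distance = 12L,
                          negatives_per_frame = 120L, stride = 1L, seed = 1L) {
  s <- list(positive_radius = as.numeric(positive_radius),
            negative_min_distance = as.numeric(negative_min_distance),
            negatives_per_frame = as.integer(negatives_per_frame),
            stride = as.integer(stride), seed = as.integer(seed))
  assert_that(s$positive_radius >= 0 && s$negatives_per_frame >= 0 &&
                s$stride >= 1L, "invalid training_spec values")
  assert_that(s$positive_radius < s$negative_min_distance,
              "positive_radius must be smaller than negative_min_distance")
  structure(s, class = "training_spec")
}

#' Assemble a labelled training set from annotated frames
#'
#' @param frames List of [gray_frame()] objects, each with `truth` set.
#' @param pattern A [sampling_pattern()].
#' @param spec A [training_spec()].
#' @return List with `features` (matrix), `labels` (+-1 vector) and `meta`
#'   (data frame `frame_id, row, col, label`), reproducible from
#'   `spec$seed`.
#' @export
build_training_set <- function(frames, pattern = sampling_pattern(),
                               spec = training_spec()) {
  for (fr in frames)
    assert_that(!is.null(fr$truth),
                sprintf("frame '%s' has no truth annotation", fr$frame_id))
  seeds <- derive_seeds(spec$seed, length(frames))
  parts <- lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    h <- nrow(fr$pixels); w <- ncol(fr$pixels)
    # positives: disc of positive_radius around each truth point
    rad <- floor(spec$positive_radius)
    offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    offs <- offs[offs$dr^2 + offs$dc^2 <= spec$positive_radius^2, ]
    pos <- unique(do.call(rbind, lapply(seq_len(nrow(fr$truth)), function(i) {
      cbind(fr$truth[i, 1] + offs$dr, fr$truth[i, 2] + offs$dc)
    })))
    pos <- pos[pos[, 1] >= 1 & pos[, 1] <= h & pos[, 2] >= 1 & pos[, 2] <= w,
               , drop = FALSE]
    # negatives: uniform on the stride grid, far from both truth points
    neg <- matrix(integer(0), 0L, 2L)
    if (spec$negatives_per_frame > 0L) {
      grid <- as.matrix(expand.grid(row = seq(1L, h, by = spec$stride),
                                    col = seq(1L, w, by = spec$stride)))
      d2min <- rep(Inf, nrow(grid))
      for (i in seq_len(nrow(fr$truth)))
        d2min <- pmin(d2min, (grid[, 1] - fr$truth[i, 1])^2 +
                              (grid[, 2] - fr$truth[i, 2])^2)
      far <- grid[d2min >= spec$negative_min_distance^2, , drop = FALSE]
      take <- min(spec$negatives_per_frame, nrow(far))
      neg <- withr::with_seed(seeds[k],
                              far[sample.int(nrow(far), take), , drop = FALSE])
    }
    pts <- rbind(pos, neg)
    lab <- c(rep(1, nrow(pos)), rep(-1, nrow(neg)))
    feats <- extract_features_batch(fr, pts, pattern)
    list(features = feats,
         meta = data.frame(frame_id = fr$frame_id, row = pts[, 1],
                           col = pts[, 2], label = lab))
  })
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  rownames(meta) <- NULL
  list(features = do.call(rbind, lapply(parts, `[[`, "features")),
       labels = meta$label, meta = meta)
}

#' Scan a frame with a trained classifier
#'
#' Classifies every pixel on the stride grid inside the region of interest
#' and returns the positives: the candidate set passed to the refinement
#' stage. Intersection-kernel models are evaluated with the fast
#' table-based decision function; baseline kernels fall back to the direct
#' expansion.
#'
#' @param frame A [gray_frame()].
#' @param model An `iksvm_model`, or precomputed `iksvm_tables`.
#' @param pattern The [sampling_pattern()] the model was trained with.
#' @param stride Grid step in pixels (default 1: every pixel).
#' @param roi Optional `c(row_min, row_max, col_min, col_max)` region;
#'   defaults to the whole image.
#' @param use_fast Use the table-based evaluation when available.
#' @return An object of class `candidate_set`: a data frame with columns
#'   `row`, `col`, `decision` (positives only) and attributes `frame_id`,
#'   `shape`, `stride`. An empty candidate set is a valid result.
#' @export
scan_frame <- function(frame, model, pattern = sampling_pattern(),
                       stride = 1L, roi = NULL, use_fast = TRUE) {
  px <- frame$pixels
  assert_that(stride >= 1L, "stride must be >= 1")
  if (is.null(roi)) roi <- c(1L, nrow(px), 1L, ncol(px))
  assert_that(roi[1] >= 1 && roi[2] <= nrow(px) &&
                roi[3] >= 1 && roi[4] <= ncol(px) &&
                roi[1] <= roi[2] && roi[3] <= roi[4],
              "roi must be a valid rectangle inside the image")
  grid <- as.matrix(expand.grid(row = seq(roi[1], roi[2], by = stride),
                                col = seq(roi[3], roi[4], by = stride)))
  feats <- extract_features_batch(frame, grid, pattern)
  h <- if (inherits(model, "iksvm_tables")) {
    decide_fast(model, feats)
  } else if (model$kernel == "intersection" && use_fast) {
    decide_fast(build_tables(model), feats)
  } else {
    decide_naive(model, feats)
  }
  keep <- h >= 0
  out <- data.frame(row = grid[keep, 1], col = grid[keep, 2],
                    decision = h[keep])
  structure(out, class = c("candidate_set", "data.frame"),
            frame_id = frame$frame_id, shape = dim(px), stride = stride)
}

#' Export a candidate set to CSV
#' @param candidates A `candidate_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  df <- data.frame(frame_id = attr(candidates, "frame_id"),
                   row = candidates$row, col = candidates$col,
                   decision_value = candidates$decision)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an inspection overlay of candidates on a frame
#'
#' Paints candidate pixels red on the grayscale frame and writes an RGB
#' PNG, for visual checks of the classifier stage.
#'
#' @param frame A [gray_frame()].
#' @param candidates A `candidate_set` for that frame.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(frame, candidates, path) {
  g <- frame$pixels / 255
  rgb <- array(g, c(dim(g), 3L))
  if (nrow(candidates) > 0) {
    idx <- cbind(candidates$row, candidates$col)
    rgb[cbind(idx, 1L)] <- 1
    rgb[cbind(idx, 2L)] <- 0
    rgb[cbind(idx, 3L)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
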