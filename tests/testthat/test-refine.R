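# Place a diamond-shaped bump of the given peak at a centre by stamping
# `peak` unit-weight candidates there (field value at the centre == peak).
stamp_points <- function(...) do.call(rbind, list(...))

test_that("block distance is the Manhattan metric", {
  expect_equal(block_distance(c(3, 4), c(3, 4)), 0)
  expect_equal(block_distance(c(0, 0), c(3, 4)), 7)
  set.seed(1)
  for (i in 1:20) {
    p <- sample(1:50, 2); q <- sample(1:50, 2)
    expect_equal(block_distance(p, q), block_distance(q, p))
    expect_equal(block_distance(p, q), sum(abs(p - q)))
  }
})

test_that("an isolated candidate stamps the full template weight at itself", {
  f <- density_field(as_candidates(matrix(c(30, 40), 1), c(64, 64)), R = 10)
  expect_equal(f$values[30, 40], 10)
  expect_equal(f$values[30, 50], 0)                # block distance 10: floor
  expect_equal(f$values[35, 45], 0)                # |5| + |5| = 10
  expect_equal(f$values[30, 49], 1)                # distance 9 -> weight 1
  expect_true(all(f$values >= 0))
})

test_that("templated stamping equals the brute-force double sum exactly", {
  set.seed(2)
  for (trial in 1:25) {
    n <- sample(1:12, 1)
    shape <- c(sample(20:40, 1), sample(20:40, 1))
    pts <- cbind(sample(shape[1], n, replace = TRUE),
                 sample(shape[2], n, replace = TRUE))
    R <- sample(c(4L, 8L, 10L), 1)
    f <- density_field(as_candidates(pts, shape), shape, R = R)
    expect_identical(f$values, brute_density(pts, shape, R))
  }
})

test_that("density field rejects out-of-shape candidates", {
  expect_error(density_field(as_candidates(matrix(c(70, 5), 1), c(64, 64)),
                             c(64, 64)),
               "outside")
})

test_that("component labelling agrees between connectivities where expected", {
  mask <- matrix(FALSE, 7, 7)
  mask[2, 2] <- TRUE; mask[3, 3] <- TRUE           # diagonal touch
  l8 <- label_components(mask, 8L)
  l4 <- label_components(mask, 4L)
  expect_equal(max(l8), 1L)
  expect_equal(max(l4), 2L)
  mask[6, 6] <- TRUE
  expect_equal(max(label_components(mask, 8L)), 2L)
})

test_that("adaptive threshold isolates the two bright clusters", {
  shape <- c(80, 80)
  bright1 <- matrix(rep(c(20, 20), 10), ncol = 2, byrow = TRUE)
  bright2 <- matrix(rep(c(20, 60), 10), ncol = 2, byrow = TRUE)
  for (k in c(0L, 1L, 3L)) {
    faint_centres <- list(c(60, 20), c(60, 45), c(60, 70))[seq_len(k)]
    faint <- do.call(rbind, lapply(faint_centres, function(p)
      matrix(rep(p, 3), ncol = 2, byrow = TRUE)))
    pts <- rbind(bright1, bright2, faint)
    f <- density_field(as_candidates(pts, shape), shape, R = 10)
    thr <- adaptive_threshold(f)
    expect_false(thr$fallback)
    expect_equal(thr$n_components, 2L)
    cents <- component_centroids(thr$components)
    cents <- cents[order(cents[, 2]), ]
    expect_lt(max(abs(cents[1, ] - c(20, 20))), 2)
    expect_lt(max(abs(cents[2, ] - c(20, 60))), 2)
    # faint bumps (peak 30 vs 100) are excluded by the returned threshold
    if (k > 0) expect_gte(thr$threshold, 30)
    # search-bound invariant
    expect_gte(thr$threshold, min(f$values))
    expect_lt(thr$threshold, max(f$values))
  }
})

test_that("a single-component field triggers the flagged fallback", {
  pts <- matrix(rep(c(10, 10), 5), ncol = 2, byrow = TRUE)
  f <- density_field(as_candidates(pts, c(30, 30)), c(30, 30), R = 10)
  thr <- adaptive_threshold(f)
  expect_true(thr$fallback)
  expect_equal(thr$n_components, 1L)
  expect_error(adaptive_threshold(density_field(
    as_candidates(matrix(numeric(0), 0, 2), c(10, 10)), c(10, 10))),
    "refinement error")
})

test_that("thresholded masks shrink as the threshold grows", {
  set.seed(3)
  pts <- cbind(sample(40, 30, replace = TRUE), sample(40, 30, replace = TRUE))
  f <- density_field(as_candidates(pts, c(40, 40)), c(40, 40), R = 8)
  hs <- sort(unique(as.vector(f$values)))
  for (i in seq_len(length(hs) - 1)) {
    hi_mask <- f$values > hs[i + 1]
    lo_mask <- f$values > hs[i]
    expect_true(all(lo_mask[hi_mask]))             # subset-wise shrinkage
  }
})

test_that("component centroids are coordinate means", {
  comps <- list(rbind(c(0, 0), c(0, 2)), rbind(c(5, 5)))
  cents <- component_centroids(comps)
  expect_equal(unname(cents[1, ]), c(0, 1))
  expect_equal(unname(cents[2, ]), c(5, 5))
  diamond <- rbind(c(9, 10), c(11, 10), c(10, 9), c(10, 11), c(10, 10))
  expect_equal(unname(component_centroids(list(diamond, rbind(c(1, 1))))[1, ]),
               c(10, 10))
  expect_error(component_centroids(list(rbind(c(1, 1)))), "two")
})

test_that("k-means refinement recovers two tight blobs", {
  set.seed(4)
  blob1 <- cbind(round(rnorm(30, 20, 1.2)), round(rnorm(30, 20, 1.2)))
  blob2 <- cbind(round(rnorm(30, 22, 1.2)), round(rnorm(30, 50, 1.2)))
  pts <- rbind(blob1, blob2)
  res <- kmeans_refine(pts, rbind(c(19, 21), c(23, 49)), scale = 15)
  expect_s3_class(res, "hinge_result")
  expect_lte(max(abs(res$centers[1, ] - colMeans(blob1))), 1)
  expect_lte(max(abs(res$centers[2, ] - colMeans(blob2))), 1)
  expect_lte(res$septal[2], res$lateral[2])        # column-order convention
  # cross-check the partition against the standard Lloyd implementation
  km <- stats::kmeans(pts, centers = rbind(c(19, 21), c(23, 49)),
                      algorithm = "Lloyd", iter.max = 100)
  ours <- res$centers[order(res$centers[, 2]), ]
  ref <- km$centers[order(km$centers[, 2]), ]
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("candidates exactly at the centres are a k-means fixed point", {
  centres <- rbind(c(10, 10), c(10, 30))
  res <- kmeans_refine(centres, centres, scale = 5)
  expect_equal(res$septal, c(10L, 10L))
  expect_equal(res$lateral, c(10L, 30L))
  expect_false(isTRUE(res$reinitialized))
})

test_that("an emptied cluster is reseeded at its initial centre and flagged", {
  pts <- rbind(c(10, 10), c(10, 11))               # all near centre 1
  res <- kmeans_refine(pts, rbind(c(10, 10), c(10, 28)), scale = 30)
  expect_true(res$reinitialized)
  expect_error(kmeans_refine(pts, rbind(c(10, 10), c(10, 10)), scale = 5),
               "distinct")
})

test_that("localization recovers the truth on a noiseless phantom", {
  params <- test_params(speckle_shape = Inf)
  train <- generate_dataset(4, params, seed = 31L)
  test <- generate_dataset(2, params, seed = 32L)
  ts <- build_training_set(train, sampling_pattern(),
                           training_spec(negatives_per_frame = 80))
  model <- ik_train(ts$features, ts$labels)
  for (fr in test) {
    res <- localize(fr, model)
    expect_true(res$detected)
    expect_lte(sqrt(sum((res$septal - fr$truth["septal", ])^2)), 4)
    expect_lte(sqrt(sum((res$lateral - fr$truth["lateral", ])^2)), 4)
    again <- localize(fr, model)
    expect_identical(res$septal, again$septal)
    expect_identical(res$lateral, again$lateral)
  }
})

test_that("localization reports no-detection instead of crashing", {
  fr <- generate_dataset(1, test_params(), seed = 33L)[[1]]
  res <- localize(fr, always_negative_model(65))
  expect_false(res$detected)
  expect_match(res$reason, "empty")
  path <- withr::local_tempfile(fileext = ".json")
  write_hinge_result(res, path)
  obj <- jsonlite::read_json(path)
  expect_false(obj$detected)
})
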