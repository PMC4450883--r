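#' Histogram intersection kernel
#'
#' `K(x, z) = sum_i min(x_i, z_i)` for nonnegative vectors. This is an
#' additive kernel: it decomposes into a sum of one-dimensional kernels,
#' which is what makes the exact fast evaluation of [decide_fast()]
#' possible.
#'
#' @param x,z Nonnegative numeric vectors of equal length.
#' @return The kernel value, a nonnegative scalar bounded by
#'   `min(sum(x), sum(z))`.
#' @export
intersection_kernel <- function(x, z) {
  assert_that(length(x) == length(z), "x and z must have equal length")
  assert_that(all(is.finite(x)) && all(is.finite(z)) &&
                min(x) >= 0 && min(z) >= 0,
              "the intersection kernel requires finite nonnegative entries")
  sum(pmin(x, z))
}

# Kernel matrix between the rows of A (n_a x d) and B (n_b x d).
kernel_gram <- function(A, B, kernel = "intersection", sigma = NULL) {
  switch(kernel,
    intersection = {
      K <- matrix(0, nrow(A), nrow(B))
      for (i in seq_len(ncol(A)))
        K <- K + outer(A[, i], B[, i], pmin)
      K
    },
    linear = tcrossprod(A, B),
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      exp(-pmax(d2, 0) / (2 * sigma^2))
    },
    stop(sprintf("unknown kernel '%s'", kernel), call. = FALSE)
  )
}

#' Train a support vector machine for hinge-point candidates
#'
#' Fits a soft-margin C-SVM in the dual over a precomputed kernel matrix
#' (SMO via \pkg{kernlab}) and repackages the solution as the support
#' vectors, the signed dual coefficients `alpha_l * y_l` and the bias `b`
#' of the kernel expansion `h(z) = sum_l alpha_l y_l K(x_l, z) + b`. The
#' histogram intersection kernel is the default; `linear` and `rbf` are
#' available behind the same interface as comparison baselines.
#'
#' @param features Numeric matrix, one example per row. Entries must be
#'   nonnegative for the intersection kernel.
#' @param labels Vector of class labels in `{-1, +1}` (positives = hinge
#'   neighbourhood).
#' @param C Soft-margin cost (box constraint `0 <= alpha_i <= C`).
#' @param kernel One of `"intersection"`, `"linear"`, `"rbf"`.
#' @param sigma RBF bandwidth (required for `kernel = "rbf"`).
#' @param layout Optional feature-layout fingerprint stored with the model
#'   (see [sampling_pattern()]); guards against train/test layout drift.
#' @return An object of class `iksvm_model` with fields `sv` (support
#'   vector matrix), `coef` (signed dual coefficients), `b`, `C`, `kernel`.
#' @export
ik_train <- function(features, labels, C = 1, kernel = "intersection",
                     sigma = NULL, layout = NULL) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  assert_that(all(labels %in% c(-1, 1)), "labels must be -1 or +1")
  assert_that(length(unique(labels)) == 2L,
              "training requires at least one example of each class")
  assert_that(all(is.finite(features)), "features must be finite")
  assert_that(C > 0, "C must be positive")
  kernel <- match.arg(kernel, c("intersection", "linear", "rbf"))
  if (kernel == "intersection")
    assert_that(min(features) >= 0,
                "the intersection kernel requires nonnegative features")
  if (kernel == "rbf")
    assert_that(is.numeric(sigma) && sigma > 0, "rbf kernel requires sigma > 0")

  K <- kernel_gram(features, features, kernel, sigma)
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                       factor(labels, levels = c(-1, 1)),
                       type = "C-svc", C = C)
  idx <- kernlab::alphaindex(fit)[[1]]
  # kernlab's decision value is K[, idx] %*% coef - b(fit); fold the sign
  # of the offset in so that h(z) = sum coef * K(sv, z) + b
  structure(list(sv = features[idx, , drop = FALSE],
                 coef = kernlab::coef(fit)[[1]],
                 b = -kernlab::b(fit),
                 C = C, kernel = kernel, sigma = sigma,
                 dim = ncol(features), layout = layout),
            class = "iksvm_model")
}

#' @export
print.iksvm_model <- function(x, ...) {
  cat(sprintf("<iksvm_model: %s kernel, %d support vectors, dim %d, C = %g>\n",
              x$kernel, nrow(x$sv), x$dim, x$C))
  invisible(x)
}

#' Decision values by direct kernel expansion
#'
#' Evaluates `h(z) = sum_l alpha_l y_l K(x_l, z) + b` by comparing the
#' query against every support vector: cost O(m * n) per query. This is
#' the reference (exact) evaluation that [decide_fast()] must reproduce;
#' it also serves the linear and RBF baseline kernels.
#'
#' @param model An [ik_train()] model.
#' @param z A feature vector, or a matrix with one query per row.
#' @return Decision value(s), one per query.
#' @export
decide_naive <- function(model, z) {
  Z <- if (is.matrix(z)) z else matrix(z, 1L)
  assert_that(ncol(Z) == model$dim,
              sprintf("query dimension %d does not match model dimension %d",
                      ncol(Z), model$dim))
  h <- drop(kernel_gram(Z, model$sv, model$kernel, model$sigma) %*% model$coef +
              model$b)
  if (is.matrix(z)) h else unname(h)
}

#' Precompute the per-dimension tables of the fast additive evaluation
#'
#' For an additive kernel the decision function splits as
#' `h(z) = sum_i h_i(z_i) + b`, with
#' `h_i(z_i) = sum_l alpha_l y_l min(z_i, x_{l,i})`. Sorting the support
#' values in each dimension and splitting the sum at the largest sorted
#' value `<= z_i` (rank `r`) gives `h_i(z_i) = A_i(r) + z_i * B_i(r)`,
#' where `A_i` is a prefix sum of `coef * sorted value` and `B_i` a suffix
#' sum of `coef`. Both depend only on the trained model, so they are
#' computed once; each query then needs only a binary search per dimension.
#'
#' @param model An intersection-kernel [ik_train()] model with at least
#'   one support vector.
#' @return An object of class `iksvm_tables` holding, per dimension, the
#'   sorted support values and the `A`/`B` partial-sum tables, plus the
#'   bias. `A_i(0) = 0` and `B_i(m) = 0` by construction; `B_i(0)` equals
#'   `sum(alpha_l y_l)` in every dimension.
#' @export
build_tables <- function(model) {
  assert_that(inherits(model, "iksvm_model"), "model must be an iksvm_model")
  assert_that(model$kernel == "intersection",
              "fast tables apply to the intersection kernel only")
  m <- nrow(model$sv)
  assert_that(m >= 1L, "model has no support vectors")
  n <- model$dim
  sorted <- matrix(0, m, n); A <- matrix(0, m, n); B <- matrix(0, m, n)
  B0 <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(model$sv[, i])
    sv <- model$sv[ord, i]
    cf <- model$coef[ord]
    sorted[, i] <- sv
    A[, i] <- cumsum(cf * sv)
    suffix <- rev(cumsum(rev(cf)))       # suffix[r] = sum_{l >= r} cf[l]
    B0[i] <- suffix[1]
    B[, i] <- c(suffix[-1], 0)           # B[r] = sum_{l > r} cf[l]
  }
  structure(list(sorted = sorted, A = A, B = B, B0 = B0,
                 b = model$b, m = m, dim = n),
            class = "iksvm_tables")
}

#' Fast exact decision values from precomputed tables
#'
#' Evaluates the intersection-kernel decision function in O(n log m) per
#' query: in each dimension a binary search locates `r`, the number of
#' sorted support values `<= z_i` (ties included), and
#' `h_i = A_i(r) + z_i * B_i(r)`. When `z_i` lies below every support
#' value, `r = 0` and `h_i = z_i * B_i(0)`; since `B_i(0) = sum alpha_l y_l`
#' is zero at the SVM optimum this reduces to `h_i = 0`, but the general
#' form keeps the fast path identical to [decide_naive()] even when the
#' solver's equality constraint holds only to tolerance.
#'
#' @param tables An [build_tables()] object.
#' @param z A feature vector, or a matrix with one query per row.
#' @param bias Bias added to the additive sum; defaults to the model bias
#'   stored in the tables.
#' @return Decision value(s), equal to [decide_naive()] up to floating-point
#'   roundoff.
#' @export
decide_fast <- function(tables, z, bias = tables$b) {
  assert_that(inherits(tables, "iksvm_tables"), "tables must be iksvm_tables")
  Z <- if (is.matrix(z)) z else matrix(z, 1L)
  assert_that(ncol(Z) == tables$dim,
              sprintf("query dimension %d does not match table dimension %d",
                      ncol(Z), tables$dim))
  h <- rep(bias, nrow(Z))
  for (i in seq_len(tables$dim)) {
    zi <- Z[, i]
    r <- findInterval(zi, tables$sorted[, i])  # largest r with sorted[r] <= zi
    below <- r == 0L
    hi <- numeric(length(zi))
    hi[below] <- zi[below] * tables$B0[i]
    if (any(!below))
      hi[!below] <- tables$A[r[!below], i] + zi[!below] * tables$B[r[!below], i]
    h <- h + hi
  }
  if (is.matrix(z)) h else unname(h)
}

#' Classify feature vectors
#'
#' Sign of the decision value; an exact zero maps to `+1` (documented
#' tie rule). Accepts either a model (any kernel, naive evaluation) or
#' precomputed tables (intersection kernel, fast evaluation).
#'
#' @param object An `iksvm_model` or `iksvm_tables`.
#' @param z Feature vector or matrix of queries (one per row).
#' @return `+1`/`-1` per query.
#' @export
ik_classify <- function(object, z) {
  h <- if (inherits(object, "iksvm_tables")) decide_fast(object, z)
       else decide_naive(object, z)
  ifelse(h >= 0, 1, -1)
}

#' Serialize a trained model to JSON
#'
#' The schema stores support vectors, signed coefficients, bias, `C`,
#' kernel name and the feature-layout fingerprint at full precision.
#' Fast-evaluation tables are rebuilt on load rather than stored.
#'
#' @param model An `iksvm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_iksvm <- function(model, path) {
  obj <- list(schema = "iksvm-model-v1",
              kernel = model$kernel, C = model$C, sigma = model$sigma,
              b = model$b, dim = model$dim, layout = model$layout,
              coef = model$coef,
              sv = apply(model$sv, 1L, identity, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_iksvm()]
#' @param path JSON model path.
#' @return An `iksvm_model`.
#' @export
read_iksvm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(obj$schema, "iksvm-model-v1"),
              "unrecognised model file schema")
  sv <- if (is.matrix(obj$sv)) obj$sv
        else if (is.list(obj$sv)) do.call(rbind, obj$sv)
        else matrix(obj$sv, 1L)
  structure(list(sv = sv, coef = obj$coef, b = obj$b, C = obj$C,
                 kernel = obj$kernel,
                 sigma = if (!is.null(obj$sigma)) obj$sigma,
                 dim = obj$dim,
                 layout = if (!is.null(obj$layout)) obj$layout),
            class = "iksvm_model")
}
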