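test_that("intersection kernel matches elementwise-minimum evaluation", {
  expect_equal(intersection_kernel(c(1, 2, 3), c(1, 2, 3)), 6)
  expect_equal(intersection_kernel(c(0, 0), c(5, 7)), 0)
  expect_equal(intersection_kernel(c(1, 4, 2), c(3, 1, 2)), 4)
  expect_error(intersection_kernel(c(1, 2), c(1, 2, 3)), "length")
  expect_error(intersection_kernel(c(-1, 2), c(1, 2)), "nonnegative")
  # symmetry and the self-similarity bound on random nonnegative pairs
  set.seed(1)
  for (i in 1:20) {
    x <- runif(10, 0, 50); z <- runif(10, 0, 50)
    expect_equal(intersection_kernel(x, z), intersection_kernel(z, x))
    expect_lte(intersection_kernel(x, z), min(sum(x), sum(z)))
  }
})

test_that("two separable points give a correct two-support-vector machine", {
  X <- matrix(c(1, 5), 2, 1)
  y <- c(-1, 1)
  m <- ik_train(X, y, C = 100)
  expect_equal(nrow(m$sv), 2L)
  expect_equal(ik_classify(m, matrix(1)), -1)
  expect_equal(ik_classify(m, matrix(5)), 1)
})

test_that("trained models satisfy the dual KKT constraints", {
  set.seed(2)
  n <- 65
  X <- rbind(matrix(runif(100 * n, 0, 80), 100),
             matrix(runif(100 * n, 60, 160), 100))
  y <- rep(c(-1, 1), each = 100)
  m <- ik_train(X, y, C = 1)
  expect_true(all(abs(m$coef) <= 1 + 1e-8))        # 0 <= alpha_i <= C
  expect_lt(abs(sum(m$coef)), 1e-6)                # sum alpha_i y_i = 0
  acc <- mean(ik_classify(m, X) == y)
  expect_gt(acc, 0.5)
  # margin condition h(x_l) y_l >= 1 - tol for non-bound support vectors
  h <- decide_naive(m, m$sv)
  ysv <- sign(m$coef)
  interior <- abs(m$coef) < 1 - 1e-6
  expect_true(all((h * ysv)[interior] >= 1 - 1e-2))  # within solver tolerance
})

test_that("training rejects degenerate inputs", {
  X <- matrix(runif(10), 10, 1)
  expect_error(ik_train(X, rep(1, 10)), "each class")
  expect_error(ik_train(X, rep(c(1, -1), 5), C = 0), "positive")
  expect_error(ik_train(-X, rep(c(1, -1), 5)), "nonnegative")
})

test_that("decision values agree with an independent SMO implementation", {
  set.seed(3)
  X <- rbind(matrix(runif(30 * 4, 0, 40), 30),
             matrix(runif(30 * 4, 30, 90), 30))
  y <- rep(c(-1, 1), each = 30)
  m <- ik_train(X, y, C = 2)
  K <- mahinge:::kernel_gram(X, X, "intersection")
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                       factor(y, levels = c(-1, 1)), type = "C-svc", C = 2)
  ref <- kernlab::predict(
    fit, kernlab::as.kernelMatrix(K[, kernlab::alphaindex(fit)[[1]],
                                    drop = FALSE]), type = "decision")
  expect_equal(decide_naive(m, X), drop(ref), tolerance = 1e-10)
})

test_that("fast tables match brute-force partial sums", {
  set.seed(4)
  m <- rand_ik_model(5, 3)
  tb <- build_tables(m)
  for (i in 1:3) {
    ord <- order(m$sv[, i])
    svs <- m$sv[ord, i]; cfs <- m$coef[ord]
    expect_equal(tb$sorted[, i], svs)
    for (r in 1:5) {
      expect_equal(tb$A[r, i], sum(cfs[seq_len(r)] * svs[seq_len(r)]))
      expect_equal(tb$B[r, i], sum(cfs[seq_len(5) > r]))
    }
    expect_equal(tb$B0[i], sum(cfs))
  }
  expect_false(is.unsorted(tb$sorted[, 1]))
  # B_i(0) is the dimension-free sum of signed coefficients
  expect_equal(tb$B0, rep(sum(m$coef), 3))
  expect_equal(tb$B[5, ], rep(0, 3))               # B_i(m) = 0 exactly
})

test_that("single-support-vector tables reduce to the closed form", {
  m <- rand_ik_model(1, 4)
  tb <- build_tables(m)
  expect_equal(tb$A[1, ], m$coef * m$sv[1, ])
  expect_equal(tb$B[1, ], rep(0, 4))
  expect_equal(tb$B0, rep(m$coef, 4))
})

test_that("naive decision reproduces the kernel expansion", {
  set.seed(5)
  m1 <- rand_ik_model(1, 6)
  z <- m1$sv[1, ]
  expect_equal(decide_naive(m1, z), m1$coef * sum(z) + m1$b)
  expect_equal(decide_naive(m1, rep(0, 6)), m1$b)
  m <- rand_ik_model(7, 6)
  z <- runif(6, 0, 255)
  manual <- sum(vapply(1:7, function(l)
    m$coef[l] * intersection_kernel(z, m$sv[l, ]), numeric(1))) + m$b
  expect_equal(decide_naive(m, z), manual)
  expect_error(decide_naive(m, runif(5)), "dimension")
})

test_that("fast evaluation is exact against the naive oracle", {
  set.seed(6)
  for (trial in 1:60) {
    m <- rand_ik_model(sample(c(1, 2, 17, 64), 1), sample(c(1, 65), 1),
                       tie_fraction = 0.3)
    tb <- build_tables(m)
    n <- m$dim; msv <- nrow(m$sv)
    Z <- matrix(runif(4 * n, -20, 300), 4, n)
    Z[1, ] <- m$sv[cbind(sample(msv, n, replace = TRUE), 1:n)]  # on ties
    Z[2, ] <- -1                                                # below all
    hN <- decide_naive(m, Z)
    hF <- decide_fast(tb, Z)
    expect_true(all(abs(hF - hN) <= 1e-9 * (1 + abs(hN))))
  }
})

test_that("each h_i is continuous and piecewise linear at the breakpoints", {
  set.seed(7)
  m <- rand_ik_model(9, 1)
  tb <- build_tables(m)
  for (v in tb$sorted[, 1]) {
    eps <- 1e-7
    left <- decide_fast(tb, matrix(v - eps))
    at <- decide_fast(tb, matrix(v))
    right <- decide_fast(tb, matrix(v + eps))
    expect_equal(left, at, tolerance = 1e-4)
    expect_equal(right, at, tolerance = 1e-4)
  }
})

test_that("queries below every support value return the bias when sum(coef)=0", {
  m <- rand_ik_model(4, 3)
  m$coef <- c(0.3, -0.3, 0.5, -0.5)               # exact zero sum
  tb <- build_tables(m)
  z <- rep(min(m$sv) - 5, 3)
  expect_equal(decide_fast(tb, z), m$b)
})

test_that("classification maps the zero decision value to +1", {
  m <- rand_ik_model(1, 2)
  m$coef <- 0; m$b <- 0                            # h == 0 everywhere
  expect_equal(ik_classify(m, c(1, 2)), 1)
  m$b <- -0.1
  expect_equal(ik_classify(m, c(1, 2)), -1)
  m$b <- 2.3
  expect_equal(ik_classify(m, c(1, 2)), 1)
})

test_that("models round-trip through the JSON schema at full precision", {
  set.seed(8)
  m <- rand_ik_model(6, 5)
  m$layout <- "r=1,3;c=1;w=3"
  path <- withr::local_tempfile(fileext = ".json")
  write_iksvm(m, path)
  back <- read_iksvm(path)
  expect_equal(back$sv, m$sv)
  expect_equal(back$coef, m$coef)
  expect_equal(back$b, m$b)
  expect_identical(back$layout, m$layout)
  z <- runif(5, 0, 255)
  expect_equal(decide_naive(back, z), decide_naive(m, z))
})
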