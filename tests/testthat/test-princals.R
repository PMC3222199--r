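test_that("all-numeric fit reproduces classical PCA of z-scored data", {
  withr::with_seed(3, {
    X <- as.data.frame(matrix(rnorm(50 * 3), 50, 3))
  })
  names(X) <- c("a", "b", "c")
  f <- fit_princals(X, ndim = 2)
  pc <- prcomp(scale(X))
  lam <- pc$sdev^2
  expect_equal(f$eigenvalues, lam[1:2], tolerance = 1e-6)
  A <- pc$rotation[, 1:2] %*% diag(sqrt(lam[1:2]))
  for (d in 1:2) if (sum(A[, d] * f$loadings[, d]) < 0) A[, d] <- -A[, d]
  expect_equal(unname(f$loadings), unname(A), tolerance = 1e-6)
  expect_equal(f$vaf_total, 100 * sum(lam[1:2]) / 3, tolerance = 1e-6)
})

test_that("single numeric variable gives loading 1 and full VAF", {
  f <- fit_princals(data.frame(x = rnorm(30)), ndim = 1)
  expect_equal(abs(unname(f$loadings[1, 1])), 1, tolerance = 1e-10)
  expect_equal(f$vaf_total, 100, tolerance = 1e-8)
})

test_that("reversing an ordinal variable's category order flips its scaling", {
  withr::with_seed(9, {
    o <- sample(1:4, 120, replace = TRUE)
    y <- o + rnorm(120, 0, 0.6)
  })
  d1 <- data.frame(o = factor(o, levels = 1:4, ordered = TRUE), y = y)
  d2 <- data.frame(o = factor(o, levels = 4:1, ordered = TRUE), y = y)
  f1 <- fit_princals(d1, ndim = 1)
  f2 <- fit_princals(d2, ndim = 1)
  expect_equal(f1$vaf_total, f2$vaf_total, tolerance = 1e-6)
  expect_equal(f1$loss_trace[length(f1$loss_trace)],
               f2$loss_trace[length(f2$loss_trace)], tolerance = 1e-6)
  q1 <- f1$quantifications$quantification
  q2 <- f2$quantifications$quantification
  expect_equal(q1, -rev(q2), tolerance = 1e-6)
})

test_that("fit invariants hold on a mixed-type cohort", {
  g <- generate_cohort(cohort_config(n = 250, outlier_spec = NULL, seed = 21))
  f <- fit_princals(g$table,
                    vars = c("four_sq", "stress_scale", "fatigue_scale",
                             "control_scale"),
                    ndim = 2)
  X <- as.matrix(f$scores[c("dim1", "dim2")])
  n <- nrow(X)
  # normalization: centered, orthonormal under X'X = N I
  expect_equal(colMeans(X), c(dim1 = 0, dim2 = 0), tolerance = 1e-10)
  expect_equal(crossprod(X), n * diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # loss trace never increases
  expect_true(all(diff(f$loss_trace) <= 1e-10))
  # ordinal quantifications nondecreasing in declared order
  for (v in unique(f$quantifications$variable)) {
    q <- f$quantifications$quantification[f$quantifications$variable == v]
    expect_true(all(diff(q) >= -1e-10))
  }
  # transformed columns have mean 0, variance 1 (population denominator)
  Tq <- as.matrix(f$transformed)
  expect_equal(unname(colMeans(Tq)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(colSums(Tq^2) / n), rep(1, 4), tolerance = 1e-10)
  # eigenvalues equal those of the correlation matrix of transformed columns
  lam <- eigen(crossprod(Tq) / n, symmetric = TRUE)$values
  expect_equal(f$eigenvalues, lam[1:2], tolerance = 1e-8)
  # lambda_d = sum of squared loadings per dimension; VAF identities
  expect_equal(unname(colSums(f$loadings^2)), f$eigenvalues, tolerance = 1e-8)
  expect_equal(f$vaf_per_dim, 100 * f$eigenvalues / 4, tolerance = 1e-10)
  expect_equal(f$vaf_total, sum(f$vaf_per_dim))
  expect_true(all(abs(f$loadings) <= 1 + 1e-8))
})

test_that("two perfectly rank-correlated ordinal variables align fully", {
  withr::with_seed(5, r <- sample(1:5, 200, replace = TRUE))
  d <- data.frame(a = factor(r, ordered = TRUE),
                  b = factor(letters[r], ordered = TRUE))
  f <- fit_princals(d, ndim = 1)
  expect_true(all(abs(f$loadings) >= 0.999))
  expect_gte(f$vaf_total, 99.9)
})

test_that("degenerate inputs are rejected by name", {
  expect_error(fit_princals(data.frame(x = rep(1, 10), y = rnorm(10)), ndim = 1),
               "x")
  expect_error(fit_princals(data.frame(x = factor(rep("a", 10)), y = rnorm(10)),
                            ndim = 1), "x")
  expect_error(fit_princals(data.frame(x = rnorm(5)), ndim = 2), "ndim")
})

test_that("centroid quantification equals per-category score means", {
  sc <- matrix(c(1, 3, -1, -3), ncol = 1)
  q <- quantify_nominal(c("a", "a", "b", "b"), sc)
  expect_equal(q$dim1, c(2, -2))
  # all respondents in one category reduces to the overall mean
  q1 <- quantify_nominal(rep("a", 4), matrix(c(-2, -1, 1, 2), ncol = 1))
  expect_equal(q1$dim1, 0)
  expect_error(quantify_nominal(factor(c("a", "a"), levels = c("a", "b")),
                                matrix(1:2, ncol = 1)), "empty category")
})

test_that("a balanced binary variable quantifies to +/- 1", {
  withr::with_seed(2, {
    b <- rep(c("lo", "hi"), each = 40)
    y <- ifelse(b == "hi", 1, -1) + rnorm(80, 0, 0.4)
  })
  f <- fit_princals(data.frame(b = factor(b, levels = c("lo", "hi"),
                                          ordered = TRUE), y = y), ndim = 1)
  q <- f$quantifications$quantification
  expect_equal(sort(q), c(-1, 1), tolerance = 1e-8)
})

test_that("object-score update satisfies its constraints and closed form", {
  withr::with_seed(8, Tq <- matrix(rnorm(60 * 4), 60, 4))
  X <- update_object_scores(Tq, ndim = 1)
  expect_equal(colMeans(X), 0, tolerance = 1e-10)
  expect_equal(as.numeric(crossprod(X)), 60, tolerance = 1e-8)
  # p = 1: proportional to the centered row mean of the quantified columns
  rm_ <- rowMeans(Tq) - mean(rowMeans(Tq))
  expect_equal(abs(cor(X[, 1], rm_)), 1, tolerance = 1e-10)
  # multi-dimension update is orthonormal
  A <- withr::with_seed(1, matrix(rnorm(12), 4, 3))
  X2 <- update_object_scores(Tq, loadings = A)
  expect_equal(crossprod(X2), 60 * diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-deficient quantified data cannot support the requested dimensions
  expect_error(update_object_scores(cbind(1:10, 2 * (1:10)),
                                    loadings = matrix(rnorm(4), 2, 2)),
               "dimensions")
})

test_that("eigenvalue-based alpha reproduces printed coefficients", {
  expect_equal(round(cronbach_alpha(4 * 0.842, 4), 3), 0.937)
  expect_equal(round(cronbach_alpha(9 * 0.701, 9), 3), 0.947)
  expect_equal(cronbach_alpha(1, 5), 0)
  expect_error(cronbach_alpha(0, 4), "lambda")
  expect_error(cronbach_alpha(2, 1), "m must be")
  # classical covariance-based alpha on a known structure
  withr::with_seed(13, {
    f <- rnorm(400)
    items <- sapply(1:3, function(i) 0.8 * f + 0.6 * rnorm(400))
  })
  a <- cronbach_alpha_classical(items)
  expect_gt(a, 0.7)
  expect_lt(a, 0.95)
})

test_that("loading classification applies the absolute threshold inclusively", {
  A <- matrix(c(0.975, 0.102, 0.4, -0.39), 2, 2,
              dimnames = list(c("total_activity", "walking"), c("d1", "d2")))
  fl <- classify_loadings(A)
  expect_true(fl$essential[fl$variable == "total_activity" & fl$dimension == "d1"])
  expect_false(fl$essential[fl$variable == "walking" & fl$dimension == "d1"])
  expect_true(fl$essential[fl$variable == "total_activity" & fl$dimension == "d2"])   # exactly 0.4
  expect_false(fl$essential[fl$variable == "walking" & fl$dimension == "d2"])  # -0.39
  expect_error(classify_loadings(A, threshold = 1.2), "threshold")
})

test_that("tidy, glance and autoplot work on a fit", {
  f <- fit_princals(data.frame(x = rnorm(40), y = rnorm(40)), ndim = 1)
  td <- tidy(f)
  expect_named(td, c("variable", "dimension", "loading", "essential"))
  gl <- glance(f)
  expect_equal(gl$ndim, 1)
  expect_s3_class(autoplot(f), "ggplot")
})
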