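test_that("correlation-mode PCA matches an independent SVD route", {
  set.seed(31)
  x <- matrix(rnorm(120), 20, 6)
  p <- chemo_pca(x, mode = "correlation")
  # prcomp goes through the SVD of the scaled data, not eigen(cor(x))
  ref <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expect_equal(p$all_eigenvalues[1:6], unname(ref$sdev^2),
               tolerance = 1e-10)
  for (j in 1:6) {
    agree <- max(abs(p$scores[, j] - ref$x[, j]))
    flipped <- max(abs(p$scores[, j] + ref$x[, j]))
    expect_lt(min(agree, flipped), 1e-8)
  }
  # covariance mode against prcomp without scaling
  p2 <- chemo_pca(x, mode = "covariance")
  ref2 <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(p2$all_eigenvalues[1:6], unname(ref2$sdev^2),
               tolerance = 1e-10)
})

test_that("PCA handles rank-1 correlation and rejects constant columns", {
  x <- cbind(a = 1:10, b = 2 * (1:10) + 3)   # perfectly correlated pair
  p <- chemo_pca(x, mode = "correlation")
  expect_equal(p$variance_explained, c(1, 0), tolerance = 1e-12)

  bad <- cbind(a = 1:10, b = rep(5, 10))
  expect_error(chemo_pca(bad, mode = "correlation"), "zero-variance.*b")
})

test_that("uncorrelated standardized variables spread variance evenly", {
  set.seed(37)
  x <- matrix(rnorm(4 * 4000), 4000, 4)
  p <- chemo_pca(x, mode = "correlation")
  expect_true(all(abs(p$variance_explained - 0.25) < 0.03))
})

test_that("correlation-mode PCA is invariant to per-variable affine maps", {
  set.seed(41)
  x <- matrix(rnorm(90), 15, 6)
  y <- sweep(sweep(x, 2, runif(6, 0.5, 20), "*"), 2, rnorm(6, 0, 10), "+")
  px <- chemo_pca(x, mode = "correlation")
  py <- chemo_pca(y, mode = "correlation")
  expect_equal(sum(px$variance_explained), 1, tolerance = 1e-10)
  for (j in seq_len(ncol(px$scores))) {
    agree <- max(abs(px$scores[, j] - py$scores[, j]))
    flipped <- max(abs(px$scores[, j] + py$scores[, j]))
    expect_lt(min(agree, flipped), 1e-8)
  }
})

test_that("linear-kernel KPCA equals correlation PCA up to sign", {
  set.seed(43)
  x <- matrix(rnorm(80), 16, 5)
  kp <- chemo_kpca(x, kernel_spec("linear"), k = 5)
  p <- chemo_pca(x, mode = "correlation", k = 5)
  for (j in 1:5) {
    agree <- max(abs(kp$scores[, j] - p$scores[, j]))
    flipped <- max(abs(kp$scores[, j] + p$scores[, j]))
    expect_lt(min(agree, flipped), 1e-8)
  }
  # eigenvalue ratios coincide too (kernel eigenvalues are (n-1)-scaled)
  expect_equal(kp$variance_explained, p$variance_explained,
               tolerance = 1e-10)
})

test_that("rbf KPCA flattens at huge bandwidth and honors duplicate rows", {
  set.seed(47)
  x <- matrix(rnorm(40), 8, 5)
  K <- chemoprint:::.kernel_matrix(x, x, kernel_spec("rbf", 1e9))
  expect_lt(max(abs(K - 1)), 1e-10)   # all-ones limit
  e1 <- eigen(K, symmetric = TRUE)$values
  expect_equal(e1[1], 8, tolerance = 1e-8)
  expect_lt(max(abs(e1[-1])), 1e-8)

  xd <- rbind(x, x[3, ])
  kp <- chemo_kpca(xd, kernel_spec("rbf", 2), k = 3, standardize = FALSE)
  expect_equal(kp$scores[9, ], kp$scores[3, ], tolerance = 1e-8)
})

test_that("discriminant separates distinct point classes and bounds rank", {
  x <- rbind(matrix(rep(c(0, 0), 5), ncol = 2, byrow = TRUE),
             matrix(rep(c(10, 10), 5), ncol = 2, byrow = TRUE))
  x <- x + matrix(rnorm(20, sd = 1e-6), 10, 2)
  fit <- discriminant(x, rep(c("a", "b"), each = 5), method = "lda")
  expect_gt(sqrt(sum((fit$class_centroids["a", ] -
                        fit$class_centroids["b", ])^2)), 0)
  expect_equal(predict(fit, x)$label, rep(c("a", "b"), each = 5))

  # three collinear classes: one informative direction, second eigen ~ 0
  set.seed(53)
  y <- cbind(rep(c(0, 5, 10), each = 4) + rnorm(12, sd = 0.01),
             rep(c(0, 5, 10), each = 4) + rnorm(12, sd = 0.01))
  f3 <- discriminant(y, rep(c("a", "b", "c"), each = 4), method = "lda")
  expect_lte(ncol(f3$projection), 2)
  expect_lt(f3$eigenvalues[2] / f3$eigenvalues[1], 1e-2)

  expect_error(discriminant(x, c(rep("a", 9), "b")), "insufficient")
  expect_error(discriminant(x, rep("a", 10)), "2 classes")
})

test_that("LDA directions agree with MASS::lda on a well-posed problem", {
  skip_if_not_installed("MASS")
  set.seed(59)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  lab <- rep(c("a", "b"), each = 20)
  fit <- discriminant(x, lab, method = "lda", lambda = 1e-8)
  ref <- MASS::lda(x, grouping = lab)
  # one discriminant direction: compare after norm/sign alignment, in the
  # original variable space (undo the internal standardization)
  w <- fit$projection[, 1] / fit$scaling$scale
  w <- w / sqrt(sum(w^2))
  v <- ref$scaling[, 1] / sqrt(sum(ref$scaling[, 1]^2))
  expect_lt(min(max(abs(w - v)), max(abs(w + v))), 1e-3)
})

test_that("kda with a linear kernel reproduces lda assignments", {
  set.seed(61)
  agree <- TRUE
  for (i in 1:50) {
    k <- sample(2:4, 1)
    n_per <- sample(4:7, 1)
    p <- sample(3:6, 1)
    centers <- matrix(rnorm(k * p, sd = 6), k, p)
    x <- do.call(rbind, lapply(1:k, function(c)
      matrix(rnorm(n_per * p, sd = 0.5), n_per, p) +
        matrix(centers[c, ], n_per, p, byrow = TRUE)))
    lab <- rep(letters[1:k], each = n_per)
    a <- predict(discriminant(x, lab, method = "lda"), x)$label
    b <- predict(discriminant(x, lab, method = "kda",
                              kernel = kernel_spec("linear")), x)$label
    agree <- agree && identical(a, b) && identical(a, lab)
  }
  expect_true(agree)
})

test_that("prediction ties go to the lexicographically smallest label", {
  x <- rbind(matrix(c(-1, 0), 4, 2, byrow = TRUE),
             matrix(c(1, 0), 4, 2, byrow = TRUE)) +
    matrix(c(0, 0, 0, 0, 1, -1, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1), 8, 2)
  lab <- rep(c("b", "a"), each = 4)   # deliberately reverse-ordered input
  fit <- discriminant(x, lab, method = "lda", lambda = 0.1)
  pr <- predict(fit, c(0, 0))
  expect_equal(unname(abs(diff(pr$distances[1, ]))), 0, tolerance = 1e-9)
  expect_equal(pr$label, "a")
  expect_error(predict(fit, c(1, 2, 3)), "3 variables")
})

test_that("held-out samples from well-separated species classify perfectly", {
  bench <- make_benchmark(seed = 42, replicates = 5)
  ft <- extract_features(bench$data, bench$targets, 0.01)
  fit <- discriminant(ft, method = "kda")
  held <- lapply(seq_along(bench$profiles), function(i)
    simulate_spectrum(bench$profiles[[i]],
                      noise_model(5, 0.02), seed = 777 + i))
  hf <- extract_features(spectrum_collection(held), bench$targets, 0.01)
  pr <- predict(fit, hf)
  expect_equal(pr$label, names(bench$profiles))
})

test_that("loocv is exact on degenerate data and near chance under label permutation", {
  # identical samples within classes, distinct classes: perfect recovery
  x <- rbind(matrix(c(0, 0), 4, 2, byrow = TRUE),
             matrix(c(8, 8), 4, 2, byrow = TRUE),
             matrix(c(-8, 8), 4, 2, byrow = TRUE))
  x <- x + matrix(rnorm(24, sd = 1e-3), 12, 2)
  lab <- rep(c("a", "b", "c"), each = 4)
  cv <- loocv(x, lab, method = "lda")
  expect_equal(cv$percent_correct, 100)
  expect_equal(unname(rowSums(cv$confusion)), c(4, 4, 4))

  # permuted labels: accuracy collapses toward 100/k
  set.seed(67)
  xr <- matrix(rnorm(40 * 6), 40, 6)
  labr <- sample(rep(c("a", "b"), each = 20))
  cvr <- loocv(xr, labr, method = "lda")
  expect_lt(cvr$percent_correct, 80)
  expect_gt(cvr$percent_correct, 15)
})

test_that("loocv is invariant to sample order and warns on size-2 classes", {
  bench <- make_benchmark(seed = 3, replicates = 3)
  ft <- extract_features(bench$data, bench$targets, 0.01)
  cv1 <- loocv(ft, method = "lda")
  set.seed(71)
  perm <- sample(nrow(ft$values))
  cv2 <- loocv(ft$values[perm, ], ft$labels[perm], method = "lda")
  expect_equal(cv2$percent_correct, cv1$percent_correct)
  expect_equal(100 * sum(diag(cv1$confusion)) / sum(cv1$confusion),
               cv1$percent_correct)

  # a size-2 class triggers the documented warning; the affected folds
  # fall back to the remaining classes' model
  x <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
             matrix(rnorm(12, 10, 0.1), 6, 2),
             matrix(rnorm(4, -10, 0.1), 2, 2))
  expect_warning(
    cvw <- loocv(x, c(rep("a", 6), rep("b", 6), rep("c", 2)),
                 method = "lda"),
    "size 2")
  # the two "c" folds cannot predict "c" and are necessarily wrong
  expect_equal(sum(cvw$predicted != cvw$truth), 2)
})
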