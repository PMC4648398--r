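# coerce a feature_table / fingerprint_matrix / matrix to a plain numeric
# matrix plus optional labels
.as_feature_matrix <- function(x, labels = NULL) {
  if (inherits(x, "feature_table") || inherits(x, "fingerprint_matrix")) {
    if (is.null(labels)) labels <- x$labels
    m <- x$values
    rownames(m) <- x$sample_ids
    colnames(m) <- sprintf("%.4f", if (!is.null(x$target_mz)) x$target_mz
                           else x$bin_centers)
  } else {
    m <- as.matrix(x)
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  }
  storage.mode(m) <- "double"
  list(values = m, labels = labels)
}

#' Specify a kernel
#'
#' @param name `"linear"` or `"rbf"` (Gaussian).
#' @param bandwidth Positive length scale for the rbf kernel, in the same
#'   units as feature-space Euclidean distance.  `NULL` requests the
#'   median-heuristic default: the median pairwise Euclidean distance of
#'   the (standardized) training features.
#' @return An object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(name = c("rbf", "linear"), bandwidth = NULL) {
  name <- match.arg(name)
  if (name == "rbf" && !is.null(bandwidth) && bandwidth <= 0)
    stop("rbf bandwidth must be positive", call. = FALSE)
  structure(list(name = name, bandwidth = bandwidth), class = "kernel_spec")
}

# kernel matrix between row sets a (n x p) and b (m x p)
.kernel_matrix <- function(a, b, kernel) {
  if (kernel$name == "linear") return(a %*% t(b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * kernel$bandwidth^2))
}

.median_heuristic <- function(x) {
  d <- stats::dist(x)
  bw <- stats::median(d[d > 0])
  if (!is.finite(bw) || bw <= 0) 1 else bw
}

#' Principal component analysis of a feature table or fingerprint matrix
#'
#' Eigendecomposition of the correlation (default) or covariance matrix of
#' the columns.  Scores are the centered -- and, in correlation mode,
#' standardized -- data projected on the eigenvector loadings;
#' `variance_explained[i]` is the i-th eigenvalue over the eigenvalue sum.
#'
#' @param x A `feature_table`, `fingerprint_matrix`, or numeric matrix
#'   (samples in rows).
#' @param mode `"correlation"` or `"covariance"`.
#' @param k Number of components to retain (default: all,
#'   `min(n - 1, p)`).
#' @return An object of class `"chemo_pca"` with `scores`, `loadings`,
#'   `eigenvalues`, `variance_explained`.
#' @examples
#' x <- matrix(rnorm(60), 10, 6)
#' p <- chemo_pca(x, mode = "correlation")
#' summary(p)
#' @export
chemo_pca <- function(x, mode = c("correlation", "covariance"), k = NULL) {
  mode <- match.arg(mode)
  fm <- .as_feature_matrix(x)
  m <- fm$values
  n <- nrow(m); p <- ncol(m)
  if (n < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  kmax <- min(n - 1, p)
  if (is.null(k)) k <- kmax
  if (k < 1 || k > kmax)
    stop(sprintf("k must be in [1, %d]", kmax), call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (mode == "correlation" && any(sds == 0))
    stop("zero-variance variable(s) in correlation mode: ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  cm <- if (mode == "correlation") stats::cor(m) else stats::cov(m)
  e <- eigen(cm, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  centered <- sweep(m, 2, colMeans(m))
  if (mode == "correlation") centered <- sweep(centered, 2, sds, "/")
  scores <- centered %*% e$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(m)
  loadings <- e$vectors[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = ev[seq_len(k)],
                 variance_explained = ev[seq_len(k)] / sum(ev),
                 all_eigenvalues = ev, mode = mode,
                 labels = fm$labels),
            class = "chemo_pca")
}

#' @export
print.chemo_pca <- function(x, ...) {
  cat(sprintf("<chemo_pca> %s mode, %d components\n", x$mode,
              ncol(x$scores)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 5)),
            collapse = ", "),
      if (length(x$variance_explained) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.chemo_pca <- function(object, ...) {
  tab <- rbind(eigenvalue = object$eigenvalues,
               prop_variance = object$variance_explained,
               cum_variance = cumsum(object$variance_explained))
  colnames(tab) <- colnames(object$scores)
  class(tab) <- c("summary.chemo_pca", class(tab))
  tab
}

#' @export
print.summary.chemo_pca <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
plot.chemo_pca <- function(x, dims = c(1, 2), ...) {
  lab <- if (is.null(x$labels)) "black" else as.factor(x$labels)
  graphics::plot(x$scores[, dims[1]], x$scores[, dims[2]],
                 col = if (is.character(lab)) lab else as.integer(lab),
                 pch = 19,
                 xlab = sprintf("%s (%.1f%%)", colnames(x$scores)[dims[1]],
                                100 * x$variance_explained[dims[1]]),
                 ylab = sprintf("%s (%.1f%%)", colnames(x$scores)[dims[2]],
                                100 * x$variance_explained[dims[2]]), ...)
  if (!is.null(x$labels))
    graphics::legend("topright", legend = levels(lab), col =
                       seq_along(levels(lab)), pch = 19, cex = 0.7)
  invisible(x)
}

#' Kernel principal component analysis
#'
#' Eigendecomposition of the double-centered kernel matrix of the
#' standardized samples.  Scores are the eigenvector columns scaled by the
#' square root of their eigenvalues; variance explained is relative to the
#' centered-kernel trace.  Numerically negative eigenvalues are clipped at
#' zero with a warning.
#'
#' @inheritParams chemo_pca
#' @param kernel A [kernel_spec()].
#' @param standardize Standardize columns (zero mean, unit variance)
#'   before evaluating the kernel.  With a linear kernel and
#'   standardization, scores equal correlation-mode PCA scores up to
#'   column sign.
#' @return An object of class `"chemo_kpca"` (also `"chemo_pca"`).
#' @export
chemo_kpca <- function(x, kernel = kernel_spec("rbf"), k = NULL,
                       standardize = TRUE) {
  stopifnot(inherits(kernel, "kernel_spec"))
  fm <- .as_feature_matrix(x)
  m <- fm$values
  n <- nrow(m)
  if (n < 2) stop("KPCA needs at least 2 samples", call. = FALSE)
  if (is.null(k)) k <- n - 1
  if (k < 1 || k > n - 1)
    stop(sprintf("k must be in [1, %d]", n - 1), call. = FALSE)
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    sds[sds == 0] <- 1
    m <- sweep(sweep(m, 2, colMeans(m)), 2, sds, "/")
  }
  if (kernel$name == "rbf" && is.null(kernel$bandwidth))
    kernel$bandwidth <- .median_heuristic(m)
  K <- .kernel_matrix(m, m, kernel)
  # double centering: remove feature-space mean
  J <- matrix(1 / n, n, n)
  Kc <- K - J %*% K - K %*% J + J %*% K %*% J
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -1e-8 * max(abs(ev))))
    warning("negative kernel eigenvalues clipped at zero")
  ev <- pmax(ev, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  colnames(scores) <- paste0("KPC", seq_len(k))
  rownames(scores) <- rownames(m)
  structure(list(scores = scores, loadings = NULL,
                 eigenvalues = ev[seq_len(k)],
                 variance_explained = ev[seq_len(k)] / sum(ev),
                 all_eigenvalues = ev, mode = "kernel", kernel = kernel,
                 labels = fm$labels),
            class = c("chemo_kpca", "chemo_pca"))
}

# per-column standardization parameters from training data
.fit_scaling <- function(m) {
  mu <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  list(center = mu, scale = sds)
}

.apply_scaling <- function(m, sc) {
  sweep(sweep(m, 2, sc$center), 2, sc$scale, "/")
}

# within- and between-class scatter of rows of (already scaled) m
.scatter <- function(m, labels) {
  classes <- sort(unique(labels))
  p <- ncol(m)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  grand <- colMeans(m)
  for (cl in classes) {
    rows <- m[labels == cl, , drop = FALSE]
    mu <- colMeans(rows)
    cent <- sweep(rows, 2, mu)
    Sw <- Sw + crossprod(cent)
    Sb <- Sb + nrow(rows) * tcrossprod(mu - grand)
  }
  list(Sw = Sw, Sb = Sb, classes = classes)
}

# leading eigenvectors of the ridge-regularized generalized eigenproblem
# Sb v = lambda (Sw + ridge I) v, via Cholesky whitening
.fisher_directions <- function(Sw, Sb, ridge, d) {
  p <- ncol(Sw)
  Swr <- Sw + diag(ridge, p)
  R <- tryCatch(chol(Swr), error = function(e)
    stop("singular within-class scatter; increase regularization lambda",
         call. = FALSE))
  Rinv <- backsolve(R, diag(p))
  M <- t(Rinv) %*% Sb %*% Rinv
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(W = Rinv %*% e$vectors[, seq_len(d), drop = FALSE],
       eigenvalues = pmax(e$values[seq_len(d)], 0))
}

#' Fit a linear or kernel Fisher discriminant model
#'
#' Finds up to `k - 1` discriminant directions (for `k` classes)
#' maximizing between-class over within-class scatter.  `method = "lda"`
#' works on the standardized features directly; `method = "kda"` solves
#' the same criterion in the kernel feature space through the dual
#' (kernelized) generalized eigenproblem, so nonlinear class boundaries in
#' feature space become linear in kernel space.  A ridge `lambda` on the
#' within-class scatter stabilizes the fit when variables outnumber
#' samples, as they typically do for spectral fingerprints.
#'
#' @param x A `feature_table`, `fingerprint_matrix`, or numeric matrix
#'   (samples in rows).
#' @param labels Class labels, one per sample (taken from `x` when
#'   present).
#' @param method `"kda"` (default) or `"lda"`.
#' @param kernel A [kernel_spec()]; used by `"kda"` only.  The rbf
#'   bandwidth defaults to the median pairwise distance of the
#'   standardized training features.
#' @param lambda Ridge on the within-class scatter; `NULL` requests the
#'   default `1e-3 * trace(scatter) / dim`.
#' @return An object of class `"discriminant"` with the projection basis,
#'   per-class centroids in discriminant space, the stored
#'   standardization, and (for kda) the retained training features and
#'   dual coefficients.
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
#' fit <- discriminant(x, rep(c("a", "b"), each = 10), method = "lda")
#' predict(fit, c(4, 4))$label
#' @export
discriminant <- function(x, labels = NULL, method = c("kda", "lda"),
                         kernel = kernel_spec("rbf"), lambda = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(kernel, "kernel_spec"))
  fm <- .as_feature_matrix(x, labels)
  m <- fm$values; labels <- as.character(fm$labels)
  if (is.null(labels) || !length(labels))
    stop("class labels are required", call. = FALSE)
  if (length(labels) != nrow(m))
    stop("labels must parallel samples", call. = FALSE)
  counts <- table(labels)
  if (length(counts) < 2)
    stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2))
    stop("insufficient replicates: every class needs >= 2 samples (",
         paste(names(counts)[counts < 2], collapse = ", "), ")",
         call. = FALSE)
  if (!is.null(lambda) && lambda < 0)
    stop("lambda must be >= 0", call. = FALSE)

  sc <- .fit_scaling(m)
  ms <- .apply_scaling(m, sc)
  classes <- sort(unique(labels))
  d <- length(classes) - 1

  if (method == "lda") {
    st <- .scatter(ms, labels)
    if (is.null(lambda)) lambda <- 1e-3 * sum(diag(st$Sw)) / ncol(ms)
    fd <- .fisher_directions(st$Sw, st$Sb, lambda, d)
    scores <- ms %*% fd$W
    proj <- fd$W
    train_feats <- NULL
  } else {
    if (kernel$name == "rbf" && is.null(kernel$bandwidth))
      kernel$bandwidth <- .median_heuristic(ms)
    K <- .kernel_matrix(ms, ms, kernel)
    n <- nrow(K)
    grand <- rowMeans(K)
    M <- matrix(0, n, n)
    N <- matrix(0, n, n)
    for (cl in classes) {
      idx <- which(labels == cl)
      mc <- rowMeans(K[, idx, drop = FALSE])
      M <- M + length(idx) * tcrossprod(mc - grand)
      Kc <- K[, idx, drop = FALSE]
      N <- N + Kc %*% (diag(length(idx)) -
                         matrix(1 / length(idx), length(idx), length(idx))) %*% t(Kc)
    }
    if (is.null(lambda)) lambda <- 1e-3 * sum(diag(N)) / n
    fd <- .fisher_directions(N, M, lambda, d)
    scores <- K %*% fd$W     # dual projection of training samples
    proj <- fd$W             # dual coefficients, one column per direction
    train_feats <- ms
  }
  colnames(scores) <- paste0("LD", seq_len(d))
  centroids <- do.call(rbind, lapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE])))
  rownames(centroids) <- classes
  structure(list(method = method, kernel = if (method == "kda") kernel,
                 projection = proj, training_features = train_feats,
                 class_centroids = centroids, classes = classes,
                 lambda = lambda, scaling = sc, scores = scores,
                 eigenvalues = fd$eigenvalues, labels = labels,
                 n_variables = ncol(m)),
            class = "discriminant")
}

#' @export
print.discriminant <- function(x, ...) {
  cat(sprintf("<discriminant> method %s, %d classes, %d variables\n",
              toupper(x$method), length(x$classes), x$n_variables))
  if (x$method == "kda")
    cat(sprintf("  kernel: %s%s\n", x$kernel$name,
                if (x$kernel$name == "rbf")
                  sprintf(" (bandwidth %.4g)", x$kernel$bandwidth) else ""))
  cat(sprintf("  lambda: %.4g\n", x$lambda))
  cat("  discriminant eigenvalue fractions:",
      paste(sprintf("%.1f%%",
                    100 * x$eigenvalues / max(sum(x$eigenvalues), 1e-300)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.discriminant <- function(object, ...) {
  # resubstitution assignment from the stored training scores
  cen <- object$class_centroids
  lab <- rownames(cen)[apply(object$scores, 1, function(s)
    which.min(sqrt(colSums((t(cen) - s)^2))))]
  out <- list(model = object,
              resubstitution_percent = 100 * mean(lab == object$labels),
              confusion = table(truth = object$labels, predicted =
                                  factor(lab, levels = object$classes)))
  class(out) <- "summary.discriminant"
  out
}

#' @export
print.summary.discriminant <- function(x, ...) {
  print(x$model)
  cat(sprintf("  resubstitution accuracy: %.2f%%\n",
              x$resubstitution_percent))
  print(x$confusion)
  invisible(x)
}

#' Classify samples with a fitted discriminant model
#'
#' Projects each sample into discriminant space and assigns the label of
#' the nearest class centroid (Euclidean distance).  Ties go to the
#' lexicographically smallest class label.
#'
#' @param object A [discriminant()] fit.
#' @param newdata A numeric vector (one sample), matrix (samples in
#'   rows), `feature_table`, or `fingerprint_matrix`.  Variables must
#'   match the training variables.
#' @param ... Unused.
#' @return A list with `label` (character vector), `distances` (samples x
#'   classes matrix), and `scores` (projection coordinates).
#' @export
predict.discriminant <- function(object, newdata, ...) {
  if (is.null(dim(newdata)) && !inherits(newdata,
                                         c("feature_table",
                                           "fingerprint_matrix")))
    newdata <- matrix(as.numeric(newdata), nrow = 1)
  fm <- .as_feature_matrix(newdata)
  m <- fm$values
  if (ncol(m) != length(object$scaling$center))
    stop(sprintf("sample has %d variables; model was trained on %d",
                 ncol(m), length(object$scaling$center)), call. = FALSE)
  ms <- .apply_scaling(m, object$scaling)
  scores <- if (object$method == "lda") {
    ms %*% object$projection
  } else {
    .kernel_matrix(ms, object$training_features, object$kernel) %*%
      object$projection
  }
  cen <- object$class_centroids
  dists <- t(apply(scores, 1, function(s)
    sqrt(colSums((t(cen) - s)^2))))
  if (nrow(scores) == 1) dists <- matrix(dists, nrow = 1,
                                         dimnames = list(NULL,
                                                         rownames(cen)))
  colnames(dists) <- rownames(cen)
  # nearest centroid; ties broken toward the lexicographically smallest
  # label (columns are already label-sorted)
  label <- rownames(cen)[apply(dists, 1, which.min)]
  list(label = label, distances = dists, scores = scores)
}

#' Leave-one-out cross-validation of a discriminant model
#'
#' Each sample in turn is held out, the model (including the feature
#' standardization, so nothing leaks from the held-out sample) is refit on
#' the remaining `n - 1` samples, and the held-out sample is classified.
#' If removing a sample leaves its class with a single member, that
#' member is excluded from the fold's training set and the fold is
#' predicted from the remaining classes' model (with a warning).
#'
#' @inheritParams discriminant
#' @return An object of class `"loocv_result"` with `predicted`, `truth`,
#'   `percent_correct` (0--100) and `confusion` (truth in rows).
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 5), 10, 2))
#' loocv(x, rep(c("a", "b"), each = 10), method = "lda")
#' @export
loocv <- function(x, labels = NULL, method = c("kda", "lda"),
                  kernel = kernel_spec("rbf"), lambda = NULL) {
  method <- match.arg(method)
  fm <- .as_feature_matrix(x, labels)
  m <- fm$values; labels <- as.character(fm$labels)
  if (is.null(labels) || !length(labels))
    stop("class labels are required", call. = FALSE)
  n <- nrow(m)
  counts <- table(labels)
  if (any(counts == 2))
    warning("class(es) of size 2: folds removing one member train ",
            "without that class (",
            paste(names(counts)[counts == 2], collapse = ", "), ")")
  predicted <- character(n)
  holdout_distance <- numeric(n)
  for (i in seq_len(n)) {
    tr_m <- m[-i, , drop = FALSE]
    tr_lab <- labels[-i]
    keep <- tr_lab %in% names(which(table(tr_lab) >= 2))
    tr_m <- tr_m[keep, , drop = FALSE]
    tr_lab <- tr_lab[keep]
    if (length(unique(tr_lab)) < 2)
      stop("fewer than 2 usable classes remain in a LOOCV fold",
           call. = FALSE)
    fit <- discriminant(tr_m, tr_lab, method = method, kernel = kernel,
                        lambda = lambda)
    pr <- predict(fit, m[i, , drop = FALSE])
    predicted[i] <- pr$label
    holdout_distance[i] <- min(pr$distances)
  }
  classes <- sort(unique(labels))
  confusion <- table(factor(labels, levels = classes),
                     factor(predicted, levels = classes),
                     dnn = c("truth", "predicted"))
  structure(list(predicted = predicted, truth = labels,
                 percent_correct = 100 * mean(predicted == labels),
                 confusion = confusion, method = method,
                 holdout_distance = holdout_distance),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s: %.2f%% correct (%d/%d)\n",
              toupper(x$method), x$percent_correct,
              sum(x$predicted == x$truth), length(x$truth)))
  print(x$confusion)
  invisible(x)
}
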