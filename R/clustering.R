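#' Uncentered correlation between two vectors
#'
#' The similarity used by the classic Cluster 3.0 program: a correlation
#' computed about zero rather than about the mean,
#' `r = (1/n) sum (x_i / s_x)(y_i / s_y)` with
#' `s_v = sqrt((1/n) sum v_i^2)`.  For non-negative abundance profiles it
#' coincides with the cosine similarity and is invariant to positive
#' rescaling of either vector, so two samples with proportional
#' fingerprints are maximally similar regardless of overall signal level.
#'
#' @param x,y Numeric vectors of equal length, not all-zero.
#' @return Similarity in `[-1, 1]`.
#' @examples
#' uncentered_correlation(c(1, 1), c(1, 0))  # 1/sqrt(2)
#' @export
uncentered_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (!length(x)) stop("vectors must be non-empty", call. = FALSE)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0)
    stop("uncentered correlation undefined for an all-zero vector",
         call. = FALSE)
  sum(x * y) / (sx * sy)
}

#' Pairwise distance matrix of fingerprint rows
#'
#' For correlation metrics the distance is `1 - r`, giving the `[0, 2]`
#' range used by Cluster 3.0; `"euclidean"` uses the ordinary norm.
#'
#' @param m A `fingerprint_matrix`, `feature_table`, or numeric matrix
#'   (samples in rows).
#' @param metric `"uncentered_correlation"` (default, the heat-map
#'   clustering convention), `"pearson"`, or `"euclidean"`.
#' @return A symmetric numeric matrix with zero diagonal; sample ids as
#'   dimnames.
#' @export
distance_matrix <- function(m, metric = c("uncentered_correlation",
                                          "pearson", "euclidean")) {
  metric <- match.arg(metric)
  fm <- .as_feature_matrix(m)
  x <- fm$values
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_len(n))
  if (metric != "euclidean") {
    zero <- rowSums(x^2) == 0
    if (any(zero))
      stop("all-zero fingerprint row(s): ",
           paste(ids[zero], collapse = ", "), call. = FALSE)
  }
  d <- switch(metric,
    uncentered_correlation = {
      xn <- x / sqrt(rowSums(x^2))
      s <- tcrossprod(xn)
      1 - pmin(pmax(s, -1), 1)
    },
    pearson = 1 - stats::cor(t(x)),
    euclidean = as.matrix(stats::dist(x)))
  diag(d) <- 0
  d[d < 0] <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Single-linkage agglomerative clustering
#'
#' Repeatedly merges the two clusters at minimum inter-cluster distance,
#' where the inter-cluster distance is the minimum over all member pairs
#' (so chains of close samples join early).  The merge height is that
#' minimum; ties are broken toward the smallest `(i, j)` index pair, which
#' makes the merge order deterministic.  Single-linkage heights are
#' non-decreasing by construction.
#'
#' @param d A symmetric distance matrix as from [distance_matrix()] (or a
#'   `dist` object).
#' @return An object of class `"chemo_dendrogram"`: `merges` is an
#'   `(n-1) x 4` matrix with columns `node_a`, `node_b`, `height`,
#'   `new_node_id`; leaves are nodes `1..n` and internal nodes number
#'   `n+1` upward; `leaf_labels` names the leaves.
#' @export
single_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be symmetric", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("sample_%03d", seq_len(n))
  # active cluster -> current node id; inter-cluster distances maintained
  # by the minimum rule
  node <- seq_len(n)
  active <- rep(TRUE, n)
  D <- d
  diag(D) <- Inf
  merges <- matrix(0, n - 1, 4,
                   dimnames = list(NULL, c("node_a", "node_b", "height",
                                           "new_node_id")))
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    h <- min(sub)
    hit <- which(sub == h, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # smallest (i, j) pair among ties
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- idx[hit[1, 1]]; j <- idx[hit[1, 2]]
    new_id <- n + step
    merges[step, ] <- c(node[i], node[j], h, new_id)
    # single linkage: distance to the union is the pairwise minimum
    D[i, ] <- pmin(D[i, ], D[j, ])
    D[, i] <- D[i, ]
    D[i, i] <- Inf
    active[j] <- FALSE
    node[i] <- new_id
  }
  structure(list(merges = merges, leaf_labels = labels, n = n),
            class = "chemo_dendrogram")
}

#' @export
print.chemo_dendrogram <- function(x, ...) {
  cat(sprintf("<chemo_dendrogram> %d leaves, %d merges, heights %.4g-%.4g\n",
              x$n, nrow(x$merges), min(x$merges[, "height"]),
              max(x$merges[, "height"])))
  invisible(x)
}

#' Convert a dendrogram to an hclust object
#'
#' @param x A `"chemo_dendrogram"`.
#' @param ... Unused.
#' @return A [stats::hclust] object (for plotting and interoperation).
#' @export
as.hclust.chemo_dendrogram <- function(x, ...) {
  n <- x$n
  # hclust convention: leaves negative, internal nodes by merge row
  conv <- function(id) ifelse(id <= n, -id, id - n)
  merge <- cbind(conv(x$merges[, "node_a"]), conv(x$merges[, "node_b"]))
  storage.mode(merge) <- "integer"
  hc <- list(merge = merge, height = x$merges[, "height"],
             order = .leaf_order(x), labels = x$leaf_labels,
             method = "single", call = match.call(),
             dist.method = "uncentered_correlation")
  class(hc) <- "hclust"
  hc
}

# leaf order by depth-first traversal of the final merge
.leaf_order <- function(x) {
  n <- x$n
  children <- vector("list", 2 * n - 1)
  for (i in seq_len(n)) children[[i]] <- i
  for (r in seq_len(nrow(x$merges)))
    children[[x$merges[r, "new_node_id"]]] <-
      c(children[[x$merges[r, "node_a"]]],
        children[[x$merges[r, "node_b"]]])
  children[[2 * n - 1]]
}

#' @export
plot.chemo_dendrogram <- function(x, ...) {
  graphics::plot(as.hclust.chemo_dendrogram(x), ...)
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are height differences between parent and child nodes,
#' so the root-to-leaf depth of every leaf equals the root merge height
#' and node heights recovered from the tree reproduce the merge heights.
#' Duplicate leaf
#' labels are disambiguated with a numeric suffix (with a warning);
#' whitespace in labels is replaced by underscores.
#'
#' @param t A `"chemo_dendrogram"`.
#' @return A single Newick string terminated by `;`.
#' @export
to_newick <- function(t) {
  stopifnot(inherits(t, "chemo_dendrogram"))
  labs <- gsub("[[:space:]]+", "_", t$leaf_labels)
  if (anyDuplicated(labs)) {
    warning("duplicate leaf labels disambiguated with suffixes")
    labs <- make.unique(labs, sep = "_")
  }
  n <- t$n
  height <- c(rep(0, n), t$merges[, "height"])
  node_str <- c(labs, character(n - 1))
  for (r in seq_len(nrow(t$merges))) {
    a <- t$merges[r, "node_a"]; b <- t$merges[r, "node_b"]
    h <- t$merges[r, "height"]
    node_str[n + r] <- sprintf("(%s:%.10g,%s:%.10g)",
                               node_str[a], h - height[a],
                               node_str[b], h - height[b])
  }
  paste0(node_str[2 * n - 1], ";")
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The cophenetic distance between two leaves is the height of their
#' lowest common ancestor merge.
#'
#' @param t A `"chemo_dendrogram"`.
#' @return Symmetric matrix of cophenetic distances with leaf labels.
#' @export
cophenetic_matrix <- function(t) {
  stopifnot(inherits(t, "chemo_dendrogram"))
  n <- t$n
  members <- vector("list", 2 * n - 1)
  for (i in seq_len(n)) members[[i]] <- i
  cm <- matrix(0, n, n, dimnames = list(t$leaf_labels, t$leaf_labels))
  for (r in seq_len(nrow(t$merges))) {
    a <- members[[t$merges[r, "node_a"]]]
    b <- members[[t$merges[r, "node_b"]]]
    cm[a, b] <- t$merges[r, "height"]
    cm[b, a] <- t$merges[r, "height"]
    members[[t$merges[r, "new_node_id"]]] <- c(a, b)
  }
  cm
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges (equivalently, the last `k - 1`
#' merges, since single-linkage heights are non-decreasing).
#'
#' @param t A `"chemo_dendrogram"`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer cluster assignment per leaf (1-based, in leaf order).
#' @export
cut_dendrogram <- function(t, k) {
  stopifnot(inherits(t, "chemo_dendrogram"))
  n <- t$n
  if (k < 1 || k > n) stop("k must be in [1, n]", call. = FALSE)
  parent <- seq_len(2 * n - 1)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- seq_len(max(n - k, 0))
  for (r in keep) {
    a <- find(t$merges[r, "node_a"]); b <- find(t$merges[r, "node_b"])
    new <- t$merges[r, "new_node_id"]
    parent[a] <- new; parent[b] <- new
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  as.integer(factor(roots, levels = unique(roots)))
}

#' Cluster purity of a labeled dendrogram cut
#'
#' Cuts the tree into `k` clusters and scores the fraction of leaves
#' belonging to their cluster's majority label.  Purity 1 at `k` equal to
#' the number of species means every species forms its own pure clade.
#'
#' @param t A `"chemo_dendrogram"`.
#' @param labels Class labels parallel to the leaves.
#' @param k Number of clusters.
#' @return Purity in `[0, 1]`.
#' @export
cluster_purity <- function(t, labels, k) {
  stopifnot(inherits(t, "chemo_dendrogram"))
  if (length(labels) != t$n)
    stop("labels must parallel leaves", call. = FALSE)
  cl <- cut_dendrogram(t, k)
  maj <- vapply(split(as.character(labels), cl),
                function(v) max(table(v)), numeric(1))
  sum(maj) / t$n
}
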