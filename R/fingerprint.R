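#' Build the full-spectrum fingerprint matrix ("heat map")
#'
#' Bins every base-peak-normalized centroid spectrum onto a common
#' half-open m/z grid (bins `[lo, lo + w)` anchored at the acquisition
#' lower bound), taking the maximum intensity per bin, then drops bins in
#' which no sample reaches `min_rel_abundance_pct`.  The result is the
#' samples-by-bins relative-abundance matrix that heat-map rendering and
#' hierarchical clustering operate on.
#'
#' @param spectra A [spectrum_collection()] of centroided, base-peak
#'   normalized spectra (values in 0--100).
#' @param bin_width_u Bin width (u).  The default of 1 u (unit-mass
#'   binning) keeps replicate peaks carrying ppm-level mass error aligned
#'   in a common bin; millidalton-level discrimination belongs to the
#'   targeted feature windows of [extract_features()], not the heat map.
#' @param min_rel_abundance_pct Retention threshold: a bin is kept if any
#'   sample reaches this relative abundance (percent).
#' @return An object of class `"fingerprint_matrix"`: list with `values`
#'   (samples x bins), `bin_centers`, `bin_width_u`, `sample_ids`,
#'   `labels`.
#' @export
build_fingerprint_matrix <- function(spectra, bin_width_u = 1.0,
                                     min_rel_abundance_pct = 1.0) {
  stopifnot(inherits(spectra, "spectrum_collection"))
  if (bin_width_u <= 0) stop("bin_width_u must be positive", call. = FALSE)
  sp <- spectra$spectra
  if (!length(sp)) stop("empty spectrum collection", call. = FALSE)
  anchor <- min(vapply(sp, function(x) x$mz_range[1], numeric(1)))
  per <- lapply(sp, function(s) {
    if (!length(s$mz)) return(list(bin = integer(0), val = numeric(0)))
    b <- .bin_index(s$mz, anchor, bin_width_u)
    f <- factor(b, levels = sort(unique(b)))
    list(bin = sort(unique(b)),
         val = as.numeric(tapply(s$intensity, f, max)))
  })
  bins <- sort(unique(unlist(lapply(per, `[[`, "bin"))))
  vals <- matrix(0, nrow = length(sp), ncol = length(bins))
  for (i in seq_along(per)) {
    j <- match(per[[i]]$bin, bins)
    vals[i, j] <- per[[i]]$val
  }
  keep <- apply(vals, 2, max) >= min_rel_abundance_pct
  vals <- vals[, keep, drop = FALSE]
  bins <- bins[keep]
  ids <- vapply(seq_along(sp), function(i) {
    id <- sp[[i]]$meta$sample_id
    if (is.null(id)) sprintf("sample_%03d", i) else as.character(id)
  }, character(1))
  structure(list(values = vals,
                 bin_centers = anchor + (bins + 0.5) * bin_width_u,
                 bin_width_u = bin_width_u,
                 sample_ids = ids,
                 labels = spectra$labels),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d samples x %d m/z bins (width %g u)\n",
              nrow(x$values), ncol(x$values), x$bin_width_u))
  if (!is.null(x$labels))
    cat("  classes:", paste(unique(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.fingerprint_matrix <- function(x) dim(x$values)

#' @export
as.matrix.fingerprint_matrix <- function(x, ...) {
  m <- x$values
  dimnames(m) <- list(x$sample_ids, sprintf("%.4f", x$bin_centers))
  m
}

#' Extract a targeted feature table
#'
#' For each target m/z, records the maximum peak intensity within
#' `[target - tol, target + tol]` per sample (0 when no peak falls in the
#' window).  Feature masses are the classification variables fed to the
#' discriminant methods.
#'
#' @param spectra A [spectrum_collection()] of centroid spectra.
#' @param target_mz Numeric vector of target m/z values, or a path to a
#'   delimited list (one m/z per line, `#` comments).
#' @param tolerance_u Half-window (u), in `[0.001, 0.05]`; windows of
#'   distinct targets must not overlap.
#' @return An object of class `"feature_table"`: list with `values`
#'   (samples x targets), `target_mz`, `tolerance_u`, `sample_ids`,
#'   `labels`.
#' @export
extract_features <- function(spectra, target_mz, tolerance_u = 0.01) {
  stopifnot(inherits(spectra, "spectrum_collection"))
  if (is.character(target_mz)) target_mz <- read_reference_masses(target_mz)
  target_mz <- sort(unique(as.numeric(target_mz)))
  if (!length(target_mz)) stop("no target masses given", call. = FALSE)
  if (tolerance_u < 0.001 || tolerance_u > 0.05)
    stop("tolerance_u must be in [0.001, 0.05]", call. = FALSE)
  if (length(target_mz) > 1) {
    gap <- diff(target_mz)
    bad <- which(gap < 2 * tolerance_u)
    if (length(bad))
      stop(sprintf(
        "target windows overlap at tolerance %g: m/z %.4f and %.4f",
        tolerance_u, target_mz[bad[1]], target_mz[bad[1] + 1]),
        call. = FALSE)
  }
  sp <- spectra$spectra
  vals <- matrix(0, nrow = length(sp), ncol = length(target_mz))
  for (i in seq_along(sp)) {
    s <- sp[[i]]
    if (!length(s$mz)) next
    for (j in seq_along(target_mz)) {
      in_win <- abs(s$mz - target_mz[j]) <= tolerance_u
      if (any(in_win)) vals[i, j] <- max(s$intensity[in_win])
    }
  }
  ids <- vapply(seq_along(sp), function(i) {
    id <- sp[[i]]$meta$sample_id
    if (is.null(id)) sprintf("sample_%03d", i) else as.character(id)
  }, character(1))
  structure(list(values = vals, target_mz = target_mz,
                 tolerance_u = tolerance_u, sample_ids = ids,
                 labels = spectra$labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d feature masses (m/z %.3f-%.3f, tol %g u)\n",
    nrow(x$values), ncol(x$values), min(x$target_mz), max(x$target_mz),
    x$tolerance_u))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) {
  m <- x$values
  dimnames(m) <- list(x$sample_ids, sprintf("%.4f", x$target_mz))
  m
}

#' Export a fingerprint matrix in the Cluster 3.0 tab-delimited dialect
#'
#' Writes a tab-delimited text file whose first header cell is `UNIQID`
#' and whose remaining header cells are the bin-center m/z values to four
#' decimals, one row per sample.  This is the format classical gene-
#' expression clustering tools ingest, with samples as the clustered
#' items.
#'
#' @param m A [build_fingerprint_matrix()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_cluster_matrix <- function(m, path) {
  stopifnot(inherits(m, "fingerprint_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("UNIQID", sprintf("%.4f", m$bin_centers)),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(m$values)))
    writeLines(paste(c(m$sample_ids[i], sprintf("%.6g", m$values[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a Cluster-3.0-dialect fingerprint matrix
#'
#' Inverse of [export_cluster_matrix()].
#'
#' @param path File path.
#' @param bin_width_u Bin width to record on the result (the dialect does
#'   not carry it).
#' @param labels Optional class labels, one per row.
#' @return A `"fingerprint_matrix"`.
#' @export
read_cluster_matrix <- function(path, bin_width_u = 1.0, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2)
    stop("cluster matrix needs a header and at least one sample row",
         call. = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "UNIQID")
    stop("not a Cluster-dialect matrix: first header cell must be UNIQID",
         call. = FALSE)
  centers <- as.numeric(hdr[-1])
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(centers))))
  if (any(is.na(vals)))
    stop("non-numeric cell in cluster matrix ", path, call. = FALSE)
  structure(list(values = vals, bin_centers = centers,
                 bin_width_u = bin_width_u, sample_ids = ids,
                 labels = labels),
            class = "fingerprint_matrix")
}

#' Plot a fingerprint matrix as a heat map
#'
#' Base-graphics rendering of the samples-by-m/z relative-abundance
#' matrix.
#'
#' @param x A `"fingerprint_matrix"`.
#' @param col Color palette.
#' @param ... Passed to [graphics::image()].
#' @export
plot.fingerprint_matrix <- function(x, col = grDevices::hcl.colors(64,
                                      "YlOrRd", rev = TRUE), ...) {
  graphics::image(x = x$bin_centers, y = seq_len(nrow(x$values)),
                  z = t(x$values), col = col,
                  xlab = "m/z", ylab = "sample", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(x$values)), labels = x$sample_ids,
                 las = 2, cex.axis = 0.6)
  invisible(x)
}
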