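#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end workflows with the same
#' defaults as the underlying functions.  Configurations round-trip
#' losslessly through their YAML file form
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param calibrant_masses Optional reference calibrant masses (numeric or
#'   path); when given, each spectrum is recalibrated against them.
#' @param calibration_degree Polynomial degree for mass calibration.
#' @param match_tol_u Calibrant matching window (u).
#' @param bin_width_u Fingerprint bin width (u).
#' @param min_rel_abundance_pct Fingerprint bin retention threshold (%).
#' @param target_mz Feature target masses (numeric or path) for
#'   classification.
#' @param tolerance_u Feature window half-width (u).
#' @param method Classifier: `"kda"` or `"lda"`.
#' @param kernel_name,kernel_bandwidth Kernel for kda.
#' @param lambda Ridge regularization (NULL = default heuristic).
#' @param metric Clustering distance metric.
#' @param seed Integer seed recorded with every run.
#' @param output_dir Optional directory for exported artifacts.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(calibrant_masses = NULL, calibration_degree = 2,
                            match_tol_u = 0.05, bin_width_u = 1.0,
                            min_rel_abundance_pct = 1.0, target_mz = NULL,
                            tolerance_u = 0.01, method = "kda",
                            kernel_name = "rbf", kernel_bandwidth = NULL,
                            lambda = NULL,
                            metric = "uncentered_correlation", seed = 1,
                            output_dir = NULL) {
  structure(list(calibrant_masses = calibrant_masses,
                 calibration_degree = calibration_degree,
                 match_tol_u = match_tol_u, bin_width_u = bin_width_u,
                 min_rel_abundance_pct = min_rel_abundance_pct,
                 target_mz = target_mz, tolerance_u = tolerance_u,
                 method = method, kernel_name = kernel_name,
                 kernel_bandwidth = kernel_bandwidth, lambda = lambda,
                 metric = metric, seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in%
                                  names(formals(pipeline_config))])
}

# shared preprocessing: centroid profile scans, optional per-spectrum
# recalibration against the configured calibrant list, then base-peak
# normalization
.preprocess_collection <- function(spectra, config, log) {
  sp <- lapply(spectra$spectra, function(s) {
    if (s$mode == "profile") s <- centroid_spectrum(s)
    if (!is.null(config$calibrant_masses)) {
      cal <- fit_calibration(s, config$calibrant_masses,
                             match_tol_u = config$match_tol_u,
                             degree = config$calibration_degree)
      s <- apply_calibration(s, cal)
    }
    normalize_base_peak(s)
  })
  log(sprintf("preprocess: %d spectra centroided+normalized%s",
              length(sp),
              if (!is.null(config$calibrant_masses)) ", recalibrated"
              else ""))
  spectrum_collection(sp, spectra$labels)
}

.kernel_from_config <- function(config) {
  kernel_spec(config$kernel_name, config$kernel_bandwidth)
}

#' Run the supervised classification workflow
#'
#' Preprocess, extract the feature table, train the discriminant model,
#' validate it by leave-one-out cross-validation, and classify any blind
#' samples.  A blind sample whose nearest-centroid distance exceeds the
#' 95th percentile of the nearest-centroid distances the training samples
#' attained as held-out samples in their own LOOCV folds is flagged as a
#' potential novel class (a screening aid, not a calibrated test;
#' held-out rather than resubstitution distances are used because
#' discriminant projections place training points unrealistically close
#' to their centroids).
#'
#' @param spectra A labeled [spectrum_collection()] (training data).
#' @param config A [pipeline_config()]; `target_mz` must be set.
#' @param blind Optional unlabeled [spectrum_collection()] to classify.
#' @return An object of class `"chemoprint_report"` with the fitted model,
#'   `loocv`, `blind` predictions (with `novel` flags), stage log and
#'   config.
#' @export
run_classification <- function(spectra, config = pipeline_config(),
                               blind = NULL) {
  stopifnot(inherits(spectra, "spectrum_collection"),
            inherits(config, "pipeline_config"))
  if (is.null(spectra$labels))
    stop("run_classification requires labeled spectra", call. = FALSE)
  if (is.null(config$target_mz))
    stop("config error: target_mz feature masses are required",
         call. = FALSE)
  lines <- character(0)
  log <- function(msg) lines <<- c(lines, msg)

  prep <- .preprocess_collection(spectra, config, log)
  feats <- extract_features(prep, config$target_mz, config$tolerance_u)
  log(sprintf("features: %d samples x %d targets (tol %g u)",
              nrow(feats$values), ncol(feats$values), feats$tolerance_u))

  model <- discriminant(feats, method = config$method,
                        kernel = .kernel_from_config(config),
                        lambda = config$lambda)
  cv <- loocv(feats, method = config$method,
              kernel = .kernel_from_config(config), lambda = config$lambda)
  log(sprintf("loocv: %.2f%% correct (%s)", cv$percent_correct,
              toupper(config$method)))

  blind_out <- NULL
  if (!is.null(blind)) {
    bprep <- .preprocess_collection(blind, config, log)
    bfeat <- extract_features(bprep, config$target_mz, config$tolerance_u)
    pred <- predict(model, bfeat)
    # novelty screen calibrated on held-out geometry: the LOOCV folds give
    # a leakage-free sample of the nearest-centroid distance a genuine
    # member of a trained class attains
    thr <- stats::quantile(cv$holdout_distance, 0.95, names = FALSE)
    min_d <- apply(pred$distances, 1, min)
    blind_out <- data.frame(sample_id = bfeat$sample_ids,
                            predicted = pred$label,
                            min_centroid_distance = min_d,
                            novel = min_d > thr)
    attr(blind_out, "distances") <- pred$distances
    attr(blind_out, "novelty_threshold") <- thr
    log(sprintf("blind: %d samples classified, %d flagged novel",
                nrow(blind_out), sum(blind_out$novel)))
  }

  files <- character(0)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(config$output_dir, "loocv_report.csv")
    utils::write.csv(data.frame(sample_id = feats$sample_ids,
                                truth = cv$truth, predicted = cv$predicted),
                     f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(config$output_dir, "confusion.csv")
    utils::write.csv(as.data.frame.matrix(cv$confusion), f)
    files <- c(files, f)
  }
  structure(list(kind = "classification", model = model, loocv = cv,
                 blind = blind_out, features = feats, log = lines,
                 files = files, config = config),
            class = "chemoprint_report")
}

#' Run the unsupervised clustering workflow
#'
#' Preprocess, build the full-spectrum fingerprint matrix, export it in
#' the Cluster-3.0 dialect, compute the distance matrix, agglomerate by
#' single linkage, and export the dendrogram as Newick.  When labels are
#' present, cluster purity at `k = number of classes` is reported.
#'
#' @param spectra A [spectrum_collection()] (labels optional).
#' @param config A [pipeline_config()].
#' @return An object of class `"chemoprint_report"` with the
#'   `fingerprint` matrix, `dendrogram`, `newick` string, `purity` (or
#'   NA), stage log and config.
#' @export
run_clustering <- function(spectra, config = pipeline_config()) {
  stopifnot(inherits(spectra, "spectrum_collection"),
            inherits(config, "pipeline_config"))
  if (length(spectra$spectra) < 3)
    stop("clustering needs at least 3 samples", call. = FALSE)
  lines <- character(0)
  log <- function(msg) lines <<- c(lines, msg)

  prep <- .preprocess_collection(spectra, config, log)
  fp <- build_fingerprint_matrix(prep, config$bin_width_u,
                                 config$min_rel_abundance_pct)
  log(sprintf("fingerprint: %d samples x %d retained bins",
              nrow(fp$values), ncol(fp$values)))
  d <- distance_matrix(fp, config$metric)
  tree <- single_linkage(d)
  nwk <- to_newick(tree)
  purity <- NA_real_
  if (!is.null(fp$labels)) {
    purity <- cluster_purity(tree, fp$labels,
                             k = length(unique(fp$labels)))
    log(sprintf("purity at k=%d: %.3f", length(unique(fp$labels)),
                purity))
  }
  files <- character(0)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(config$output_dir, "fingerprint_cluster.txt")
    export_cluster_matrix(fp, f); files <- c(files, f)
    f <- file.path(config$output_dir, "dendrogram.nwk")
    writeLines(nwk, f); files <- c(files, f)
    f <- file.path(config$output_dir, "merges.csv")
    utils::write.csv(as.data.frame(tree$merges), f, row.names = FALSE)
    files <- c(files, f)
  }
  structure(list(kind = "clustering", fingerprint = fp, distance = d,
                 dendrogram = tree, newick = nwk, purity = purity,
                 log = lines, files = files, config = config),
            class = "chemoprint_report")
}

#' @export
print.chemoprint_report <- function(x, ...) {
  cat(sprintf("<chemoprint_report> %s workflow\n", x$kind))
  for (l in x$log) cat(" -", l, "\n")
  if (x$kind == "classification") {
    cat(sprintf("  LOOCV: %.2f%%\n", x$loocv$percent_correct))
    if (!is.null(x$blind)) {
      cat("  blind predictions:\n")
      print(x$blind, row.names = FALSE)
    }
  } else {
    cat(sprintf("  dendrogram: %d leaves", x$dendrogram$n))
    if (!is.na(x$purity)) cat(sprintf(", purity %.3f", x$purity))
    cat("\n")
  }
  if (length(x$files)) cat("  files:", paste(x$files, collapse = ", "),
                           "\n")
  invisible(x)
}
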