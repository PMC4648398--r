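#' Construct a mass spectrum
#'
#' A `spectrum` is the basic unit of data: parallel vectors of m/z and
#' intensity plus acquisition metadata.  Centroid spectra have strictly
#' increasing m/z; profile (continuum) spectra allow repeated m/z values.
#'
#' @param mz Numeric vector of mass-to-charge values (u).
#' @param intensity Numeric vector of non-negative abundances, same length
#'   as `mz`.
#' @param mode `"centroid"` or `"profile"`.
#' @param polarity `"positive"` or `"negative"`.
#' @param mz_range Declared acquisition range, length-2 numeric.  All peaks
#'   must fall inside it.  Defaults to m/z 60--1000, the usual ambient
#'   TOF acquisition window.
#' @param meta Named list of metadata (`sample_id`, `species_label`,
#'   `replicate_index`, `gas_temperature_C`, ...).
#' @return An object of class `"spectrum"`.
#' @examples
#' s <- spectrum(c(100, 200), c(5, 10))
#' s
#' @export
spectrum <- function(mz, intensity, mode = c("centroid", "profile"),
                     polarity = c("positive", "negative"),
                     mz_range = c(60, 1000), meta = list()) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("mz and intensity must be finite", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (length(mz) > 1) {
    d <- diff(mz)
    if (mode == "centroid" && any(d <= 0))
      stop("centroid spectrum requires strictly increasing m/z", call. = FALSE)
    if (mode == "profile" && any(d < 0))
      stop("profile spectrum requires non-decreasing m/z", call. = FALSE)
  }
  if (length(mz) && (min(mz) < mz_range[1] || max(mz) > mz_range[2]))
    stop(sprintf("m/z values outside declared acquisition range [%g, %g]",
                 mz_range[1], mz_range[2]), call. = FALSE)
  structure(list(mz = mz, intensity = intensity, mode = mode,
                 polarity = polarity, mz_range = as.numeric(mz_range),
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %s mode, %d peaks",
              x$polarity, x$mode, length(x$mz)))
  if (length(x$mz))
    cat(sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)))
  cat("\n")
  if (!is.null(x$meta$sample_id))
    cat("  sample_id:", x$meta$sample_id, "\n")
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$mz)

#' Construct a spectrum collection
#'
#' An ordered set of spectra sharing one polarity, with optional parallel
#' class labels.
#'
#' @param spectra List of [spectrum()] objects.
#' @param labels Optional character vector of class labels, one per
#'   spectrum.
#' @return An object of class `"spectrum_collection"`.
#' @export
spectrum_collection <- function(spectra, labels = NULL) {
  if (!length(spectra)) stop("empty spectrum collection", call. = FALSE)
  if (!all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("all elements must be spectrum objects", call. = FALSE)
  pol <- unique(vapply(spectra, `[[`, character(1), "polarity"))
  if (length(pol) > 1)
    stop("all spectra in a collection must share polarity", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(spectra))
      stop("labels must parallel spectra", call. = FALSE)
  }
  structure(list(spectra = spectra, labels = labels),
            class = "spectrum_collection")
}

#' @export
print.spectrum_collection <- function(x, ...) {
  cat(sprintf("<spectrum_collection> %d spectra", length(x$spectra)))
  if (!is.null(x$labels))
    cat(sprintf(", %d classes", length(unique(x$labels))))
  cat("\n")
  invisible(x)
}

#' @export
length.spectrum_collection <- function(x) length(x$spectra)

#' Read a centroided peak list from delimited text
#'
#' Supports the two-column (m/z, intensity) dialect commonly used for
#' supplementary peak tables, with comma or tab delimiter auto-detected
#' and an optional header line.  Rows sharing an m/z value are merged by
#' summing their intensities: duplicates represent split centroids of a
#' single ion.
#'
#' @param path File path.
#' @param dialect `"two_column"` (delimiter auto-detected) or
#'   `"labeled_csv"` (comma-separated with `mz`/`intensity` named columns).
#' @param mz_range Acquisition range passed to [spectrum()].
#' @param ... Further arguments passed to [spectrum()] (e.g. `polarity`,
#'   `meta`).
#' @return A centroid-mode [spectrum()] sorted by ascending m/z.
#' @export
read_peaklist <- function(path, dialect = c("two_column", "labeled_csv"),
                          mz_range = c(60, 1000), ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty peak list: ", path, call. = FALSE)

  if (dialect == "labeled_csv") {
    df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
    if (!all(c("mz", "intensity") %in% names(df)))
      stop("labeled_csv dialect requires 'mz' and 'intensity' columns",
           call. = FALSE)
    mz <- as.numeric(df$mz); inten <- as.numeric(df$intensity)
    if (any(is.na(mz)) || any(is.na(inten)))
      stop("non-numeric value in peak list ", path, call. = FALSE)
  } else {
    sep <- if (grepl("\t", lines[1])) "\t" else ","
    first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
    has_header <- any(is.na(suppressWarnings(as.numeric(first))))
    if (has_header) lines <- lines[-1]
    if (!length(lines)) stop("empty peak list: ", path, call. = FALSE)
    mz <- numeric(length(lines)); inten <- numeric(length(lines))
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], sep, fixed = TRUE)[[1]]
      v <- suppressWarnings(as.numeric(f))
      if (length(v) < 2 || any(is.na(v[1:2])))
        stop(sprintf("malformed peak-list row at line %d of %s: '%s'",
                     i + has_header, path, lines[i]), call. = FALSE)
      mz[i] <- v[1]; inten[i] <- v[2]
    }
  }
  o <- order(mz)
  mz <- mz[o]; inten <- inten[o]
  # merge exact duplicate m/z rows (split centroids of one ion)
  if (anyDuplicated(mz)) {
    inten <- as.numeric(tapply(inten, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  spectrum(mz, inten, mode = "centroid", mz_range = mz_range, ...)
}

#' Write a centroided peak list as delimited text
#'
#' Emits a commented header plus comma-separated `mz,intensity` rows with
#' nine decimal places, so a write/read round trip preserves values to
#' well below the mass tolerances used anywhere downstream.
#'
#' @param s A centroid [spectrum()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_peaklist <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mz,intensity", con)
  if (length(s$mz))
    writeLines(sprintf("%.9f,%.9f", s$mz, s$intensity), con)
  invisible(path)
}

#' Read profile spectra from an mzML file
#'
#' Reads every MS1 scan of a well-formed mzML file, preserving acquisition
#' order, one profile-mode spectrum per scan.  Requires the `mzR` package.
#'
#' @param path Path to an mzML file.
#' @param polarity Polarity to record on the spectra (mzML polarity codes
#'   are used when present).
#' @param mz_range Acquisition range; defaults to the observed data range
#'   padded to at least m/z 60--1000.
#' @return A [spectrum_collection()] of profile-mode spectra.
#' @export
read_profile_mzml <- function(path, polarity = c("positive", "negative"),
                              mz_range = NULL) {
  polarity <- match.arg(polarity)
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  h <- tryCatch(mzR::openMSfile(path),
                error = function(e) stop("invalid mzML file ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(h))
  if (length(h) < 1)
    stop("mzML file contains no spectra: ", path, call. = FALSE)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  if (is.null(mz_range)) {
    allmz <- unlist(lapply(pk, function(m) m[, 1]))
    mz_range <- if (length(allmz))
      c(min(60, floor(min(allmz))), max(1000, ceiling(max(allmz))))
    else c(60, 1000)
  }
  spectra <- lapply(seq_along(pk), function(i) {
    m <- pk[[i]]
    spectrum(m[, 1], m[, 2], mode = "profile", polarity = polarity,
             mz_range = mz_range,
             meta = list(sample_id = sprintf("scan_%03d", i),
                         replicate_index = i))
  })
  spectrum_collection(spectra)
}
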