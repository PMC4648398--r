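#' Centroid a profile spectrum
#'
#' Each local intensity maximum above the threshold becomes one centroid
#' peak.  The centroid m/z is the intensity-weighted mean over the
#' contiguous region of points at or above half the local maximum (the
#' FWHM region); the centroid intensity is that region's summed intensity.
#'
#' @param s A profile-mode [spectrum()] with at least 3 points.
#' @param min_rel_height Minimum apex height as a fraction of the base
#'   peak, in `[0, 1)`.  Apices below it are discarded.
#' @return A centroid-mode [spectrum()].
#' @export
centroid_spectrum <- function(s, min_rel_height = 0.01) {
  stopifnot(inherits(s, "spectrum"))
  if (s$mode != "profile")
    stop("centroid_spectrum requires a profile spectrum", call. = FALSE)
  if (min_rel_height < 0 || min_rel_height >= 1)
    stop("min_rel_height must be in [0, 1)", call. = FALSE)
  n <- length(s$mz)
  if (n < 3)
    stop("profile spectrum with fewer than 3 points cannot be centroided",
         call. = FALSE)
  y <- s$intensity; x <- s$mz
  if (max(y) <= 0)
    return(spectrum(numeric(0), numeric(0), mode = "centroid",
                    polarity = s$polarity, mz_range = s$mz_range,
                    meta = s$meta))
  thr <- min_rel_height * max(y)
  # local maxima: strictly above the left neighbour, at least the right
  apex <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  apex <- apex[y[apex] > thr & y[apex] > 0]
  cmz <- numeric(0); cint <- numeric(0)
  for (a in apex) {
    half <- y[a] / 2
    lo <- a
    while (lo > 1 && y[lo - 1] >= half && y[lo - 1] <= y[lo]) lo <- lo - 1
    hi <- a
    while (hi < n && y[hi + 1] >= half && y[hi + 1] <= y[hi]) hi <- hi + 1
    idx <- lo:hi
    w <- y[idx]
    cmz <- c(cmz, sum(x[idx] * w) / sum(w))
    cint <- c(cint, sum(w))
  }
  o <- order(cmz)
  cmz <- cmz[o]; cint <- cint[o]
  keep <- !duplicated(cmz)
  spectrum(cmz[keep], cint[keep], mode = "centroid", polarity = s$polarity,
           mz_range = s$mz_range, meta = s$meta)
}

#' Fit a polynomial mass-calibration model
#'
#' Matches each theoretical calibrant mass to its nearest observed peak
#' within `match_tol_u`, then least-squares fits a polynomial mapping
#' measured m/z to reference m/z.  Calibration standards such as
#' poly(ethylene glycol) 600 give a ladder of known masses across the
#' acquisition range; a degree-2 polynomial absorbs the typical residual
#' TOF drift.
#'
#' @param s A centroid [spectrum()] containing the calibrant peaks.
#' @param ref Numeric vector of strictly increasing theoretical calibrant
#'   m/z values, or a path readable by [read_reference_masses()].
#' @param match_tol_u Mass window (u) for matching references to peaks.
#' @param degree Polynomial degree, 1--3.
#' @return An object of class `"mass_calibration"` with elements
#'   `coefficients` (ascending degree), `n_matched`, `rms_residual_u`,
#'   and the matched (measured, reference) pairs.
#' @export
fit_calibration <- function(s, ref, match_tol_u = 0.05, degree = 2) {
  stopifnot(inherits(s, "spectrum"))
  if (is.character(ref)) ref <- read_reference_masses(ref)
  ref <- as.numeric(ref)
  if (is.unsorted(ref, strictly = TRUE))
    stop("reference masses must be strictly increasing", call. = FALSE)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3", call. = FALSE)
  if (!length(s$mz)) stop("calibrant spectrum has no peaks", call. = FALSE)
  measured <- vapply(ref, function(r) {
    i <- which.min(abs(s$mz - r))
    if (abs(s$mz[i] - r) <= match_tol_u) s$mz[i] else NA_real_
  }, numeric(1))
  ok <- !is.na(measured)
  if (sum(ok) < degree + 1)
    stop(sprintf(
      "calibration failed: %d calibrant peaks matched, need at least %d",
      sum(ok), degree + 1), call. = FALSE)
  m <- measured[ok]; r <- ref[ok]
  X <- outer(m, 0:degree, `^`)
  beta <- qr.coef(qr(X), r)
  res <- r - drop(X %*% beta)
  structure(list(coefficients = unname(beta),
                 degree = degree,
                 n_matched = sum(ok),
                 rms_residual_u = sqrt(mean(res^2)),
                 measured = m, reference = r),
            class = "mass_calibration")
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf(
    "<mass_calibration> degree %d, %d calibrant peaks, RMS residual %.3g u\n",
    x$degree, x$n_matched, x$rms_residual_u))
  cat("  coefficients (ascending degree):",
      paste(signif(x$coefficients, 8), collapse = ", "), "\n")
  invisible(x)
}

#' Predict calibrated m/z from measured m/z
#'
#' @param object A `"mass_calibration"` model.
#' @param newdata Numeric vector of measured m/z values.
#' @param ... Unused.
#' @return Calibrated m/z values.
#' @export
predict.mass_calibration <- function(object, newdata, ...) {
  drop(outer(as.numeric(newdata), 0:object$degree, `^`) %*%
         object$coefficients)
}

#' Apply a mass-calibration model to a spectrum
#'
#' Maps every m/z through the fitted polynomial, leaving intensities
#' untouched.  The mapping must be monotone increasing over the spectrum's
#' m/z range; a non-monotone fit (possible for an overfitted high-degree
#' polynomial) is rejected rather than silently reordering peaks.
#'
#' @param s A [spectrum()].
#' @param model A `"mass_calibration"` from [fit_calibration()].
#' @return The calibrated spectrum.
#' @export
apply_calibration <- function(s, model) {
  stopifnot(inherits(s, "spectrum"), inherits(model, "mass_calibration"))
  if (!length(s$mz)) return(s)
  new_mz <- predict(model, s$mz)
  if (length(new_mz) > 1 && any(diff(new_mz) <= 0) &&
      !any(diff(s$mz) <= 0))
    stop("calibration rejected: mapping is not monotone over the data range",
         call. = FALSE)
  rng <- range(c(s$mz_range, new_mz))
  spectrum(new_mz, s$intensity, mode = s$mode, polarity = s$polarity,
           mz_range = rng, meta = s$meta)
}

#' Read a reference mass list from delimited text
#'
#' One m/z per line; `#` starts a comment.
#'
#' @param path File path.
#' @return Strictly increasing numeric vector of reference masses.
#' @export
read_reference_masses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  v <- suppressWarnings(as.numeric(lines))
  if (any(is.na(v)))
    stop("non-numeric line in reference mass list ", path, call. = FALSE)
  sort(v)
}

# bin index on the half-open grid [anchor + k*w, anchor + (k+1)*w)
.bin_index <- function(mz, anchor, width) floor((mz - anchor) / width)

# pool a centroid spectrum onto the grid: per-bin summed intensity and
# intensity-weighted mean m/z
.bin_spectrum <- function(s, anchor, width) {
  if (!length(s$mz))
    return(list(bin = integer(0), intensity = numeric(0), mz = numeric(0)))
  b <- .bin_index(s$mz, anchor, width)
  f <- factor(b, levels = sort(unique(b)))
  inten <- as.numeric(tapply(s$intensity, f, sum))
  wmz <- as.numeric(tapply(seq_along(b), f, function(i) {
    w <- s$intensity[i]
    if (sum(w) > 0) sum(s$mz[i] * w) / sum(w) else mean(s$mz[i])
  }))
  list(bin = sort(unique(b)), intensity = inten, mz = wmz)
}

#' Average replicate spectra on a common m/z grid
#'
#' Pools the centroid peaks of all spectra onto a half-open grid of width
#' `grid_width_u` anchored at the acquisition-range lower bound.  The
#' per-bin intensity is the arithmetic mean over all spectra, counting a
#' spectrum with no peak in the bin as zero; the reported m/z is the
#' intensity-weighted mean of the contributing peaks.
#'
#' @param spectra A [spectrum_collection()] of centroid spectra.
#' @param grid_width_u Bin width (u).
#' @return A single averaged centroid [spectrum()].
#' @export
average_spectra <- function(spectra, grid_width_u = 0.005) {
  stopifnot(inherits(spectra, "spectrum_collection"))
  sp <- spectra$spectra
  if (!length(sp)) stop("empty spectrum collection", call. = FALSE)
  if (any(vapply(sp, `[[`, character(1), "mode") != "centroid"))
    stop("average_spectra requires centroid spectra", call. = FALSE)
  anchor <- min(vapply(sp, function(x) x$mz_range[1], numeric(1)))
  n <- length(sp)
  binned <- lapply(sp, .bin_spectrum, anchor = anchor, width = grid_width_u)
  all_bins <- sort(unique(unlist(lapply(binned, `[[`, "bin"))))
  if (!length(all_bins)) {
    return(spectrum(numeric(0), numeric(0), mode = "centroid",
                    polarity = sp[[1]]$polarity, mz_range = sp[[1]]$mz_range))
  }
  inten <- numeric(length(all_bins))
  wsum <- numeric(length(all_bins))   # intensity-weighted m/z accumulator
  for (b in binned) {
    i <- match(b$bin, all_bins)
    inten[i] <- inten[i] + b$intensity
    wsum[i] <- wsum[i] + b$mz * b$intensity
  }
  mzv <- ifelse(inten > 0, wsum / inten,
                anchor + (all_bins + 0.5) * grid_width_u)
  keep <- inten > 0
  rng <- range(vapply(sp, function(x) x$mz_range, numeric(2)))
  spectrum(mzv[keep], inten[keep] / n, mode = "centroid",
           polarity = sp[[1]]$polarity, mz_range = rng,
           meta = list(sample_id = "average", n_averaged = n))
}

#' Subtract a background spectrum
#'
#' Both spectra are pooled onto the same half-open grid; per bin the
#' result is `max(0, sample - background)` and emptied bins are dropped.
#'
#' @param s Sample centroid [spectrum()].
#' @param bg Background centroid [spectrum()] (blank acquisition or
#'   pre-sample scans).
#' @param grid_width_u Bin width (u).
#' @return Background-subtracted centroid [spectrum()].
#' @export
subtract_background <- function(s, bg, grid_width_u = 0.005) {
  stopifnot(inherits(s, "spectrum"), inherits(bg, "spectrum"))
  if (s$mode != "centroid" || bg$mode != "centroid")
    stop("subtract_background requires centroid spectra", call. = FALSE)
  anchor <- min(s$mz_range[1], bg$mz_range[1])
  bs <- .bin_spectrum(s, anchor, grid_width_u)
  bb <- .bin_spectrum(bg, anchor, grid_width_u)
  sub <- bs$intensity - ifelse(is.na(match(bs$bin, bb$bin)), 0,
                               bb$intensity[match(bs$bin, bb$bin)])
  keep <- sub > 0
  spectrum(bs$mz[keep], sub[keep], mode = "centroid",
           polarity = s$polarity, mz_range = s$mz_range, meta = s$meta)
}

#' Normalize a spectrum to its base peak
#'
#' Rescales intensities so the most intense peak (the base peak) equals
#' 100, putting all samples on a common relative-abundance scale for
#' fingerprint comparison.
#'
#' @param s A [spectrum()] with at least one peak of positive intensity.
#' @return The normalized spectrum (relative abundance, percent).
#' @export
normalize_base_peak <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (!length(s$mz) || max(s$intensity) <= 0)
    stop("cannot base-peak normalize a spectrum with no positive intensity",
         call. = FALSE)
  spectrum(s$mz, 100 * s$intensity / max(s$intensity), mode = s$mode,
           polarity = s$polarity, mz_range = s$mz_range, meta = s$meta)
}
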