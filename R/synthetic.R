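# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# monoisotopic constants (u): proton mass, and O2 plus one electron for
# oxygen-anion attachment
.MASS_PROTON <- 1.007276
.MASS_O2_ANION <- 31.989829 + 0.000549

#' Adduct ion m/z from a neutral monoisotopic mass
#'
#' Singly charged adducts only: protonation (`M+H`), deprotonation
#' (`M-H`), and oxygen-anion attachment (`M+O2-`), the negative-mode route
#' by which large nonpolar alkanes and lipids are detected.
#'
#' @param neutral_mass Neutral monoisotopic mass (u), positive.
#' @param adduct `"M+H"`, `"M-H"`, or `"M+O2-"`.
#' @return Ion m/z (u).
#' @examples
#' adduct_mz(366.42254, "M+O2-")  # a C26 alkane observed as [M + O2]-
#' @export
adduct_mz <- function(neutral_mass, adduct = c("M+H", "M-H", "M+O2-")) {
  adduct <- match.arg(adduct)
  if (any(neutral_mass <= 0))
    stop("neutral mass must be positive", call. = FALSE)
  switch(adduct,
         "M+H" = neutral_mass + .MASS_PROTON,
         "M-H" = neutral_mass - .MASS_PROTON,
         "M+O2-" = neutral_mass + .MASS_O2_ANION)
}

#' Construct a species chemotype profile
#'
#' @param name Species name.
#' @param compounds Data frame with columns `mass` (neutral monoisotopic,
#'   u, in (50, 1000)), `adduct`, `mean_log10` (mean log10 abundance),
#'   `cv` (abundance coefficient of variation, >= 0).
#' @param polarity `"positive"` or `"negative"`.
#' @return An object of class `"species_profile"`.
#' @export
species_profile <- function(name, compounds,
                            polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  req <- c("mass", "adduct", "mean_log10", "cv")
  if (!all(req %in% names(compounds)))
    stop("compounds needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!nrow(compounds)) stop("profile needs >= 1 compound", call. = FALSE)
  if (any(compounds$mass <= 50 | compounds$mass >= 1000))
    stop("compound masses must lie in (50, 1000) u", call. = FALSE)
  if (any(compounds$cv < 0)) stop("cv must be >= 0", call. = FALSE)
  structure(list(name = name,
                 compounds = compounds[order(compounds$mass), ,
                                       drop = FALSE],
                 polarity = polarity),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: %d compounds (%s mode)\n",
              x$name, nrow(x$compounds), x$polarity))
  invisible(x)
}

#' Noise model for spectrum simulation
#'
#' @param mass_error_ppm_sd Gaussian mass-error standard deviation (ppm).
#' @param dropout_probability Probability a compound is missed in one
#'   acquisition, in `[0, 1)`.
#' @param baseline_peak_rate Expected number of spurious baseline peaks
#'   per spectrum (Poisson).
#' @param baseline_rel_intensity_max Maximum spurious-peak intensity as a
#'   percent of the base peak.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(mass_error_ppm_sd = 5, dropout_probability = 0.02,
                        baseline_peak_rate = 0,
                        baseline_rel_intensity_max = 2) {
  if (mass_error_ppm_sd < 0 || baseline_peak_rate < 0 ||
      baseline_rel_intensity_max < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  if (dropout_probability < 0 || dropout_probability >= 1)
    stop("dropout_probability must be in [0, 1)", call. = FALSE)
  structure(list(mass_error_ppm_sd = mass_error_ppm_sd,
                 dropout_probability = dropout_probability,
                 baseline_peak_rate = baseline_peak_rate,
                 baseline_rel_intensity_max = baseline_rel_intensity_max),
            class = "noise_model")
}

#' Generate species chemotype profiles
#'
#' Builds `n_species` profiles over a common chemistry: a shared compound
#' pool (fraction `shared_fraction` of each profile) observed by every
#' species but at species-specific mean abundances offset by
#' `+/- separation` log10 units, plus private compounds unique to each
#' species.  `separation = 0` with `shared_fraction = 1` yields
#' statistically exchangeable species -- the synonym scenario in which two
#' names denote one chemotype.
#'
#' @param n_species Number of species (>= 2).
#' @param compounds_per_species Compounds per profile.
#' @param shared_fraction Fraction of each profile drawn from the shared
#'   pool, in `[0, 1]`.
#' @param separation Between-species abundance offset applied to shared
#'   compounds (log10 units).
#' @param cv Within-species abundance coefficient of variation.
#' @param polarity Ion polarity; chooses the adduct (`M+H` positive,
#'   `M+O2-` negative, emulating alkane detection).
#' @param mass_range Neutral-mass sampling range (u).
#' @param seed Integer seed; profiles are fully reproducible from it.
#' @return List of [species_profile()] objects named `species_01`, ...
#' @export
make_species_profiles <- function(n_species, compounds_per_species = 25,
                                  shared_fraction = 0.5, separation = 1.0,
                                  cv = 0.1,
                                  polarity = c("positive", "negative"),
                                  mass_range = c(80, 900), seed = 1) {
  polarity <- match.arg(polarity)
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]", call. = FALSE)
  adduct <- if (polarity == "positive") "M+H" else "M+O2-"
  n_shared <- round(shared_fraction * compounds_per_species)
  n_private <- compounds_per_species - n_shared
  .with_seed(seed, {
    shared_mass <- sort(stats::runif(n_shared, mass_range[1], mass_range[2]))
    shared_base <- stats::runif(n_shared, 3.5, 5)
    profiles <- vector("list", n_species)
    for (s in seq_len(n_species)) {
      sh <- if (n_shared) data.frame(
        mass = shared_mass, adduct = adduct,
        mean_log10 = shared_base +
          separation * sample(c(-1, 1), n_shared, replace = TRUE),
        cv = cv) else NULL
      pr <- if (n_private) data.frame(
        mass = stats::runif(n_private, mass_range[1], mass_range[2]),
        adduct = adduct,
        mean_log10 = stats::runif(n_private, 3.5, 5),
        cv = cv) else NULL
      profiles[[s]] <- species_profile(sprintf("species_%02d", s),
                                       rbind(sh, pr), polarity)
    }
    names(profiles) <- vapply(profiles, `[[`, character(1), "name")
    profiles
  })
}

#' Simulate one acquisition of a species profile
#'
#' Each compound not lost to dropout emits one centroid peak at its adduct
#' m/z perturbed by Gaussian ppm mass error.  Intensity is lognormal about
#' the compound's mean log10 abundance with the compound's coefficient of
#' variation on the linear abundance scale, i.e. a log10 standard
#' deviation of `sqrt(log(1 + cv^2)) / log(10)` (about `0.043` for
#' `cv = 0.1`, a 10% shot-to-shot spread).  Poisson-many spurious baseline
#' peaks at uniform m/z are added, then the spectrum is base-peak
#' normalized.  If every compound drops out the draw is repeated once
#' before failing.
#'
#' @param p A [species_profile()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param mz_range Acquisition range (u).
#' @param meta Metadata list stored on the spectrum.
#' @return A centroid, base-peak-normalized [spectrum()].
#' @export
simulate_spectrum <- function(p, noise = noise_model(), seed = 1,
                              mz_range = c(60, 1000), meta = list()) {
  stopifnot(inherits(p, "species_profile"), inherits(noise, "noise_model"))
  .with_seed(seed, {
    draw <- function() {
      cm <- p$compounds
      keep <- stats::runif(nrow(cm)) >= noise$dropout_probability
      cm <- cm[keep, , drop = FALSE]
      if (!nrow(cm)) return(NULL)
      mz0 <- vapply(seq_len(nrow(cm)), function(i)
        adduct_mz(cm$mass[i], cm$adduct[i]), numeric(1))
      mz <- mz0 * (1 + stats::rnorm(length(mz0)) *
                     noise$mass_error_ppm_sd * 1e-6)
      sd_log10 <- sqrt(log(1 + cm$cv^2)) / log(10)
      inten <- 10^stats::rnorm(nrow(cm), cm$mean_log10, sd_log10)
      nb <- stats::rpois(1, noise$baseline_peak_rate)
      if (nb > 0) {
        mz <- c(mz, stats::runif(nb, mz_range[1], mz_range[2]))
        inten <- c(inten, stats::runif(nb, 0,
                                       noise$baseline_rel_intensity_max /
                                         100 * max(inten)))
      }
      list(mz = mz, intensity = inten)
    }
    pk <- draw()
    if (is.null(pk)) pk <- draw()
    if (is.null(pk))
      stop("all compounds dropped out twice; empty simulated spectrum",
           call. = FALSE)
    o <- order(pk$mz)
    mz <- pk$mz[o]; inten <- pk$intensity[o]
    if (anyDuplicated(mz)) {
      inten <- as.numeric(tapply(inten, factor(mz, levels = unique(mz)),
                                 sum))
      mz <- unique(mz)
    }
    mz <- pmin(pmax(mz, mz_range[1]), mz_range[2])
    if (anyDuplicated(mz)) { inten <- inten[!duplicated(mz)]
                             mz <- unique(mz) }
    meta$species_label <- p$name
    normalize_base_peak(
      spectrum(mz, inten, mode = "centroid", polarity = p$polarity,
               mz_range = mz_range, meta = meta))
  })
}

# deterministic per-spectrum stream: independent of other replicates
.spectrum_seed <- function(master, species_idx, replicate_idx) {
  as.integer((as.double(master) * 2654435 + species_idx * 104729 +
                replicate_idx * 7919) %% 2147483647)
}

#' Simulate a labeled replicate dataset
#'
#' Draws `replicates_per_species` independent acquisitions of every
#' profile.  Each spectrum gets its own RNG stream derived from the master
#' seed and its (species, replicate) indices, so adding or removing one
#' replicate never perturbs the others.
#'
#' @param profiles List of [species_profile()] objects.
#' @param replicates_per_species Replicates per species (>= 2).
#' @param noise A [noise_model()].
#' @param seed Master integer seed.
#' @param mz_range Acquisition range (u).
#' @return A labeled [spectrum_collection()]; labels are the profile
#'   names in block order.
#' @export
simulate_dataset <- function(profiles, replicates_per_species = 5,
                             noise = noise_model(), seed = 1,
                             mz_range = c(60, 1000)) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  if (replicates_per_species < 2)
    stop("replicates_per_species must be >= 2", call. = FALSE)
  spectra <- list()
  labels <- character(0)
  for (s in seq_along(profiles)) {
    for (r in seq_len(replicates_per_species)) {
      sp <- simulate_spectrum(
        profiles[[s]], noise,
        seed = .spectrum_seed(seed, s, r), mz_range = mz_range,
        meta = list(sample_id = sprintf("%s_r%02d", profiles[[s]]$name, r),
                    replicate_index = r))
      spectra <- c(spectra, list(sp))
      labels <- c(labels, profiles[[s]]$name)
    }
  }
  spectrum_collection(spectra, labels)
}

#' Target feature masses of a profile set
#'
#' The union of all profiles' adduct ion m/z values, the natural feature
#' list for supervised classification of simulated data.
#'
#' @param profiles List of [species_profile()] objects.
#' @param min_gap_u Targets closer than this are collapsed to their mean
#'   so feature windows stay disjoint.
#' @return Ascending numeric vector of target m/z values.
#' @export
profile_feature_masses <- function(profiles, min_gap_u = 0.021) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  mz <- sort(unique(unlist(lapply(profiles, function(p)
    vapply(seq_len(nrow(p$compounds)), function(i)
      adduct_mz(p$compounds$mass[i], p$compounds$adduct[i]), numeric(1))))))
  # collapse near-coincident targets
  out <- numeric(0)
  grp <- c(mz[1])
  for (v in mz[-1]) {
    if (v - grp[length(grp)] < min_gap_u) grp <- c(grp, v)
    else { out <- c(out, mean(grp)); grp <- v }
  }
  c(out, mean(grp))
}

#' Write species profiles as a delimited compound table
#'
#' @param profiles List of [species_profile()] objects.
#' @param path Output path (CSV with columns species, polarity, mass,
#'   adduct, mean_log10, cv).
#' @return Invisibly, `path`.
#' @export
write_species_profiles <- function(profiles, path) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    cbind(species = p$name, polarity = p$polarity, p$compounds)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read species profiles from a delimited compound table
#'
#' @param path Path written by [write_species_profiles()].
#' @return List of [species_profile()] objects.
#' @export
read_species_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$species), function(d)
    species_profile(d$species[1],
                    d[, c("mass", "adduct", "mean_log10", "cv")],
                    polarity = d$polarity[1]))
}

#' Write a dataset as peak-list files plus a labels manifest
#'
#' @param spectra A labeled [spectrum_collection()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path (`labels.csv` with columns
#'   `file,label`).
#' @export
write_dataset <- function(spectra, dir) {
  stopifnot(inherits(spectra, "spectrum_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(spectra$spectra))
  for (i in seq_along(spectra$spectra)) {
    s <- spectra$spectra[[i]]
    id <- s$meta$sample_id
    if (is.null(id)) id <- sprintf("sample_%03d", i)
    files[i] <- paste0(id, ".csv")
    write_peaklist(s, file.path(dir, files[i]))
  }
  manifest <- file.path(dir, "labels.csv")
  utils::write.csv(
    data.frame(file = files,
               label = if (is.null(spectra$labels)) NA else spectra$labels),
    manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing peak lists and `labels.csv`.
#' @param mz_range Acquisition range passed to [read_peaklist()].
#' @param polarity Polarity to record.
#' @return A [spectrum_collection()].
#' @export
read_dataset <- function(dir, mz_range = c(60, 1000),
                         polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  manifest <- file.path(dir, "labels.csv")
  if (!file.exists(manifest))
    stop("no labels.csv manifest in ", dir, call. = FALSE)
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(nrow(df)), function(i)
    read_peaklist(file.path(dir, df$file[i]), mz_range = mz_range,
                  polarity = polarity,
                  meta = list(sample_id = sub("\\.csv$", "", df$file[i]))))
  labels <- if (all(is.na(df$label))) NULL else df$label
  spectrum_collection(spectra, labels)
}
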