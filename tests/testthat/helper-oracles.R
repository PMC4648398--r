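# Independent brute-force reference implementations used as oracles.
# They deliberately take the naive route (explicit double/triple loops)
# so they share no code path with the package.

# uncentered-correlation distance matrix by explicit double loop
bf_uncentered_dist <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(x[i, ] * x[j, ])
    den <- sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2))
    d[i, j] <- 1 - num / den
  }
  diag(d) <- 0
  d
}

# O(n^3) single-linkage agglomerator over explicit cluster member lists
bf_single_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dc <- min(d[clusters[[i]], clusters[[j]]])
        if (dc < best) { best <- dc; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# naive per-window feature scan
bf_extract <- function(mz, intensity, targets, tol) {
  out <- numeric(length(targets))
  for (j in seq_along(targets)) {
    best <- 0
    for (i in seq_along(mz)) {
      if (mz[i] >= targets[j] - tol && mz[i] <= targets[j] + tol &&
          intensity[i] > best)
        best <- intensity[i]
    }
    out[j] <- best
  }
  out
}

# standard 5-species benchmark dataset (well-separated chemotypes)
make_benchmark <- function(seed = 42, replicates = 5) {
  prof <- make_species_profiles(5, compounds_per_species = 25,
                                shared_fraction = 0.5, separation = 1.0,
                                cv = 0.1, seed = seed)
  ds <- simulate_dataset(prof, replicates,
                         noise_model(mass_error_ppm_sd = 5,
                                     dropout_probability = 0.02),
                         seed = seed)
  list(profiles = prof, data = ds,
       targets = profile_feature_masses(prof))
}

# one sample spectrum = base-peak-normalized average of `scans` replicate
# acquisitions, the way heat-map rows are produced from 1-Hz scan data
make_averaged_samples <- function(profiles, samples_per_species = 5,
                                  scans = 5, seed = 42) {
  spectra <- list(); labels <- character(0)
  for (i in seq_along(profiles)) {
    for (j in seq_len(samples_per_species)) {
      sc <- lapply(seq_len(scans), function(r)
        simulate_spectrum(profiles[[i]],
                          noise_model(mass_error_ppm_sd = 5,
                                      dropout_probability = 0.02),
                          seed = seed + 100000L * i + 1000L * j + r))
      avg <- average_spectra(spectrum_collection(sc), grid_width_u = 0.01)
      avg$meta$sample_id <- sprintf("%s_s%02d", profiles[[i]]$name, j)
      spectra <- c(spectra, list(normalize_base_peak(avg)))
      labels <- c(labels, profiles[[i]]$name)
    }
  }
  spectrum_collection(spectra, labels)
}

# synonym scenario: two labels over one chemotype plus one distinct species
make_synonym_dataset <- function(seed = 7, replicates = 12) {
  base <- make_species_profiles(2, compounds_per_species = 25,
                                shared_fraction = 0.5, separation = 1.0,
                                cv = 0.1, seed = seed)
  syn <- list(base[[1]], base[[1]], base[[2]])
  syn[[1]]$name <- "granA"; syn[[2]]$name <- "granB"
  syn[[3]]$name <- "other"
  ds <- simulate_dataset(syn, replicates,
                         noise_model(mass_error_ppm_sd = 5,
                                     dropout_probability = 0.02),
                         seed = seed)
  list(profiles = syn, data = ds, targets = profile_feature_masses(syn))
}
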