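profile_from <- function(mz, y, ...) spectrum(mz, y, mode = "profile", ...)

test_that("centroiding recovers apex of a symmetric peak and drops flat noise", {
  # symmetric triangle apexed at 150: weighted mean = apex
  k <- -10:10
  mz <- 150 + k * 0.002
  y <- (100 - 9 * abs(k)) * (abs(k) <= 10)
  s <- centroid_spectrum(profile_from(mz, y))
  expect_length(s$mz, 1)
  expect_equal(s$mz, 150, tolerance = 1e-9)
  expect_equal(s$mode, "centroid")

  # flat zero profile: nothing to centroid
  z <- centroid_spectrum(profile_from(seq(100, 101, 0.01),
                                      rep(0, 101)))
  expect_length(z$mz, 0)

  expect_error(centroid_spectrum(profile_from(c(100, 101), c(1, 2))),
               "fewer than 3")
  expect_error(centroid_spectrum(spectrum(100, 1)), "profile")
})

test_that("two close Gaussians centroid to their analytic FWHM-weighted means", {
  mu <- c(100.00, 100.10); sigma <- 0.01
  grid <- seq(99.9, 100.2, by = 0.002)
  y <- 100 * (exp(-(grid - mu[1])^2 / (2 * sigma^2)) +
                exp(-(grid - mu[2])^2 / (2 * sigma^2)))
  s <- centroid_spectrum(profile_from(grid, y))
  expect_length(s$mz, 2)
  # oracle: weighted mean over the sampled above-half-max region of each peak
  oracle <- vapply(mu, function(m) {
    g <- 100 * exp(-(grid - m)^2 / (2 * sigma^2))
    region <- g >= max(g) / 2 & abs(grid - m) < 0.05
    sum(grid[region] * y[region]) / sum(y[region])
  }, numeric(1))
  expect_lt(max(abs(s$mz - oracle)), 5e-4)
})

test_that("centroiding is intensity-scale invariant", {
  set.seed(3)
  grid <- seq(200, 201, by = 0.002)
  y <- rexp(length(grid)) +
    50 * exp(-(grid - 200.4)^2 / (2 * 0.008^2)) +
    80 * exp(-(grid - 200.7)^2 / (2 * 0.008^2))
  s1 <- centroid_spectrum(profile_from(grid, y))
  s2 <- centroid_spectrum(profile_from(grid, 7.5 * y))
  expect_equal(s2$mz, s1$mz)
  expect_equal(s2$intensity, 7.5 * s1$intensity)
})

test_that("calibration recovers linear offsets and the identity exactly", {
  ref <- seq(100, 900, by = 100)
  obs <- spectrum(ref + 0.010, rep(100, 9))
  cal <- fit_calibration(obs, ref, degree = 1)
  expect_equal(cal$coefficients, c(-0.010, 1.0), tolerance = 1e-9)
  expect_lt(cal$rms_residual_u, 1e-9)
  expect_equal(cal$n_matched, 9)

  cal_id <- fit_calibration(spectrum(ref, rep(1, 9)), ref, degree = 1)
  expect_equal(cal_id$coefficients, c(0, 1), tolerance = 1e-9)

  expect_error(fit_calibration(spectrum(c(100, 500), c(1, 1)),
                               ref, degree = 2),
               "calibration failed: 2")
})

test_that("quadratic drift is recovered within 0.1 mDa on held-out masses", {
  drift <- function(m) m + 5e-9 * m^2   # ppm-scale quadratic drift
  ref <- seq(100, 1000, by = 100)
  hold <- c(150, 450, 750)
  obs <- spectrum(sort(drift(ref)), rep(100, length(ref)),
                  mz_range = c(60, 1100))
  cal <- fit_calibration(obs, ref, degree = 2)
  expect_lt(max(abs(predict(cal, drift(hold)) - hold)), 1e-4)

  # apply_calibration closes the loop on a full drifted spectrum
  set.seed(8)
  truth <- sort(runif(60, 80, 950))
  drifted <- spectrum(drift(truth), rep(1, 60), mz_range = c(60, 1010))
  calibrated <- apply_calibration(drifted, cal)
  expect_lt(max(abs(calibrated$mz - truth)), 1e-4)
  expect_equal(calibrated$intensity, drifted$intensity)
})

test_that("identity and offset calibrations map spectra as stated", {
  s <- spectrum(c(100, 200), c(1, 2))
  ident <- structure(list(coefficients = c(0, 1), degree = 1L,
                          n_matched = 2L, rms_residual_u = 0),
                     class = "mass_calibration")
  expect_equal(apply_calibration(s, ident)$mz, c(100, 200))
  offset <- structure(list(coefficients = c(0.010, 1), degree = 1L,
                           n_matched = 2L, rms_residual_u = 0),
                      class = "mass_calibration")
  expect_equal(apply_calibration(s, offset)$mz, c(100.010, 200.010))
  # decreasing map is rejected
  flip <- structure(list(coefficients = c(1000, -1), degree = 1L,
                         n_matched = 2L, rms_residual_u = 0),
                    class = "mass_calibration")
  expect_error(apply_calibration(s, flip), "monotone")
})

test_that("reference mass lists read with comments and sorting", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# calibrant ladder", "300.2", "100.1  # low mass",
               "", "609.2812"), f)
  expect_equal(read_reference_masses(f), c(100.1, 300.2, 609.2812))
})

test_that("spectral averaging matches a brute-force per-bin mean", {
  s <- spectrum(c(100.001, 250.503, 700.2), c(10, 40, 5))
  # averaging a spectrum with itself reproduces it (same grid cells)
  avg <- average_spectra(spectrum_collection(list(s, s)),
                         grid_width_u = 0.01)
  expect_equal(avg$intensity, s$intensity)
  expect_equal(avg$mz, s$mz, tolerance = 1e-9)

  # two spectra, one shared bin: arithmetic mean
  a <- spectrum(100.002, 10); b <- spectrum(100.004, 20)
  avg <- average_spectra(spectrum_collection(list(a, b)),
                         grid_width_u = 0.01)
  expect_equal(avg$intensity, 15)

  # Poisson-jittered replicates vs naive double loop
  set.seed(21)
  base_mz <- sort(runif(30, 80, 950))
  reps <- lapply(1:5, function(i) {
    keep <- runif(30) > 0.2
    spectrum(base_mz[keep], rpois(sum(keep), 50) + 1)
  })
  w <- 0.05
  avg <- average_spectra(spectrum_collection(reps), grid_width_u = w)
  # oracle: accumulate per-bin sums across spectra with explicit loops
  bins <- new.env()
  for (r in reps) for (i in seq_along(r$mz)) {
    key <- as.character(floor((r$mz[i] - 60) / w))
    bins[[key]] <- (if (is.null(bins[[key]])) 0 else bins[[key]]) +
      r$intensity[i]
  }
  oracle <- sort(vapply(ls(bins), function(k) bins[[k]] / 5, numeric(1)))
  expect_equal(sort(avg$intensity), unname(oracle), tolerance = 1e-12)

  # permutation invariance
  avg2 <- average_spectra(spectrum_collection(rev(reps)), grid_width_u = w)
  expect_equal(avg2$mz, avg$mz)
  expect_equal(avg2$intensity, avg$intensity)
})

test_that("background subtraction clamps at zero and drops emptied bins", {
  s <- spectrum(c(100, 200), c(50, 10))
  bg <- spectrum(200, 25)
  out <- subtract_background(s, bg, grid_width_u = 1.0)
  expect_equal(length(out$mz), 1)
  expect_equal(out$intensity, 50)
  expect_true(abs(out$mz - 100) < 1.0)

  # self-subtraction empties the spectrum
  expect_length(subtract_background(s, s, grid_width_u = 1.0)$mz, 0)

  # empty background leaves the spectrum unchanged (up to grid pooling)
  empty <- spectrum(numeric(0), numeric(0))
  out <- subtract_background(s, empty, grid_width_u = 1.0)
  expect_equal(out$intensity, c(50, 10))

  # never negative, over random pairs
  set.seed(4)
  for (i in 1:10) {
    a <- spectrum(sort(sample(seq(100, 900, 0.5), 40)), rexp(40) * 100)
    b <- spectrum(sort(sample(seq(100, 900, 0.5), 40)), rexp(40) * 100)
    expect_true(all(subtract_background(a, b, 1.0)$intensity >= 0))
  }
})

test_that("base-peak normalization rescales to 100 and is idempotent", {
  s <- normalize_base_peak(spectrum(c(100, 200), c(5, 10)))
  expect_equal(s$intensity, c(50, 100))
  expect_equal(normalize_base_peak(spectrum(500, 7))$intensity, 100)
  expect_equal(normalize_base_peak(s)$intensity, s$intensity)
  expect_error(normalize_base_peak(spectrum(100, 0)), "normalize")
})
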