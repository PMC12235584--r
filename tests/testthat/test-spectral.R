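# Dispersion calibration, spectrum extraction, Gaussian peak fitting and
# the QC filter.

test_that("quadratic calibration through three lamp lines interpolates exactly", {
  # argon-lamp lines; synthetic quadratic pixel positions
  lam <- c(435, 586, 763)
  px <- 10 + 0.3 * lam + 1e-4 * lam^2
  cal <- calibrate_dispersion(px, lam, order = 2)
  expect_equal(max(abs(cal$residuals)), 0, tolerance = 1e-9)
  expect_equal(wavelength_at(cal, px), lam, tolerance = 1e-9)
})

test_that("affine synthetic dispersion is recovered to machine precision", {
  s <- 3.17; b <- 448.2
  px <- seq(20, 90, by = 10)
  cal <- calibrate_dispersion(px, b + s * px, order = 1)
  expect_equal(cal$coefficients, c(b, s), tolerance = 1e-12)
  expect_equal(max(abs(cal$residuals)), 0, tolerance = 1e-10)
})

test_that("degenerate or non-monotone calibrations error out", {
  expect_error(calibrate_dispersion(c(10, 10), c(500, 600), order = 1),
               "degenerate")
  # a mapping that turns over inside the working range
  expect_error(dispersion_cal(c(620, 0.1, -0.05)), "monotone")
})

test_that("calibration round-trips wavelength -> pixel -> wavelength", {
  cal2 <- calibrate_dispersion(c(30, 55, 85), c(550, 620, 700), order = 2)
  for (cal in list(dispersion_cal(c(450, 3.2)), cal2)) {
    lam <- seq(550, 700, by = 5)
    expect_equal(wavelength_at(cal, pixel_at(cal, lam)), lam,
                 tolerance = 1e-9)
  }
})

test_that("extraction finds a no-noise spectrum at the true wavelength", {
  cfg <- sim_config(fov_px = 140, background_rate = 0, n_frames = 1,
                    seed = SUITE_SEED)
  ev <- data.frame(frame = 1, particle = 1, x = 20 * 90, y = 70 * 90,
                   photons = 2000, wavelength = 620)
  mv <- render_movie(ev, cfg, noise = FALSE)
  loc <- data.frame(frame = 1, x = 20 * 90, y = 70 * 90)
  sf <- extract_spectrum(loc, mv$spectral[, , 1], cfg$dispersion,
                         cfg$pixel_size)
  # spectrum maximum within half a spectral pixel of the true wavelength
  half_px_nm <- dispersion_slope(cfg$dispersion) / 2
  peak_sample <- sf$spectrum$wavelength[which.max(sf$spectrum$intensity)]
  expect_lt(abs(peak_sample - 620), half_px_nm + 1e-9)
  expect_false(sf$off_chip)
})

test_that("photon split fractions are honoured on no-noise data", {
  cfg <- sim_config(fov_px = 160, background_rate = 0, n_frames = 1,
                    seed = SUITE_SEED)
  ev <- data.frame(frame = 1, particle = 1, x = 25 * 90, y = 80 * 90,
                   photons = 3000, wavelength = 625)
  mv <- render_movie(ev, cfg, noise = FALSE)
  locs <- detect_and_fit(mv$spatial, cfg$pixel_size)
  # transverse window wide enough to capture the full PSF (the 5 px default
  # deliberately clips ~8% of the transverse tails)
  sf <- extract_spectrum(locs[1, ], mv$spectral[, , 1], cfg$dispersion,
                         cfg$pixel_size, window = 11)
  expect_equal(sf$photons_spectral / locs$intensity[1], 0.32 / 0.41,
               tolerance = 0.03)
})

test_that("pure background extracts to near-zero spectral photons", {
  set.seed(SUITE_SEED)
  cal <- dispersion_cal(c(450, 3.2))
  resid <- replicate(50, {
    frame <- matrix(rpois(140 * 140, 2), 140, 140)
    loc <- data.frame(frame = 1, x = runif(1, 10, 40) * 90,
                      y = runif(1, 20, 120) * 90)
    sf <- extract_spectrum(loc, frame, cal, 90)
    sf$photons_spectral / nrow(sf$spectrum)  # mean count per sample
  })
  expect_lt(abs(mean(resid)), 1)
})

test_that("Gaussian peak fitting recovers center, uncertainty and centroid", {
  lam <- seq(551, 699, by = 2.8)
  noiseless <- structure(list(
    frame = 1, x = 0, y = 0,
    spectrum = data.frame(wavelength = lam,
                          intensity = 900 * exp(-(lam - 620)^2 / (2 * 19^2))),
    photons_spectral = 5000, off_chip = FALSE,
    peak_wavelength = NA_real_, centroid_wavelength = NA_real_,
    peak_uncertainty = NA_real_, fit_sigma = NA_real_,
    passed_qc = NA, qc_reason = NA_character_), class = "spectral_fit")
  ft <- fit_peak(noiseless)
  expect_equal(ft$peak_wavelength, 620, tolerance = 0.1 / 620)
  # symmetric spectrum: centroid equals peak (up to support truncation)
  expect_equal(ft$centroid_wavelength, 620, tolerance = 1e-3)
  expect_equal(ft$fit_sigma, 19, tolerance = 0.01)

  # skewed two-Gaussian spectrum: centroid from the closed-form mixture mean
  mix <- noiseless
  mix$spectrum$intensity <- 700 * exp(-(lam - 590)^2 / (2 * 12^2)) +
    300 * exp(-(lam - 650)^2 / (2 * 25^2))
  mf <- fit_peak(mix)
  oracle_centroid <- sum(lam * mix$spectrum$intensity) /
    sum(mix$spectrum$intensity)
  expect_equal(mf$centroid_wavelength, oracle_centroid, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mf$centroid_wavelength, mf$peak_wavelength,
                                tolerance = 1e-3)))
  expect_gte(mf$peak_wavelength, min(lam)); expect_lte(mf$peak_wavelength, max(lam))
})

test_that("peak bias stays under 1 nm and SE scales as photons^-1/2", {
  set.seed(SUITE_SEED)
  lam <- seq(551, 699, by = 2.8)
  run_level <- function(photons, n_rep) {
    est <- replicate(n_rep, {
      shape <- exp(-(lam - 612)^2 / (2 * 19^2))
      expected <- photons * shape / sum(shape)
      sf <- structure(list(
        frame = 1, x = 0, y = 0,
        spectrum = data.frame(wavelength = lam,
                              intensity = rpois(length(lam), expected)),
        photons_spectral = photons, off_chip = FALSE,
        peak_wavelength = NA_real_, centroid_wavelength = NA_real_,
        peak_uncertainty = NA_real_, fit_sigma = NA_real_,
        passed_qc = NA, qc_reason = NA_character_), class = "spectral_fit")
      ft <- fit_peak(sf)
      c(ft$peak_wavelength, ft$peak_uncertainty)
    })
    list(bias = mean(est[1, ]) - 612, sd = sd(est[1, ]),
         se_reported = mean(est[2, ]))
  }
  lo <- run_level(300, 200)
  hi <- run_level(4 * 300, 200)
  expect_lt(abs(lo$bias), 1)
  expect_lt(abs(hi$bias), 1)
  # quadrupling photons halves the spread
  expect_equal(lo$sd / hi$sd, 2, tolerance = 0.3)
  # reported SE tracks the empirical spread
  expect_equal(lo$se_reported / lo$sd, 1, tolerance = 0.35)
})

test_that("the QC filter applies the printed boundaries literally", {
  mk <- function(unc, ph) data.frame(
    loc_id = seq_along(unc), frame = 1, x = 0, y = 0,
    peak_wavelength = 612, centroid_wavelength = 612, fit_sigma = 19,
    peak_uncertainty = unc, photons_spatial = 800, photons_spectral = ph,
    off_chip = FALSE, passed_qc = NA, qc_reason = NA_character_)
  fits <- mk(unc = c(40.0, 40.0 + 1e-9, 45, 10, 10, 10),
             ph = c(1000, 1000, 1000, 300, 299, 1e4))
  out <- qc_filter(fits)
  expect_identical(out$passed_qc, c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  # wavelengths are never mutated, survivors are a subset
  expect_identical(out$peak_wavelength, fits$peak_wavelength)
  expect_identical(out$centroid_wavelength, fits$centroid_wavelength)
  surv <- qc_pass(out)
  expect_true(all(surv$loc_id %in% fits$loc_id))
  # off-chip spectra and failed fits never pass
  bad <- mk(10, 1000); bad$off_chip <- TRUE
  expect_false(any(qc_filter(bad)$passed_qc))
  failed <- mk(10, 1000)
  failed$passed_qc <- FALSE; failed$qc_reason <- "peak fit did not converge"
  expect_false(any(qc_filter(failed)$passed_qc))
  # width-based filtering mode uses the fitted sigma instead
  wide <- mk(10, 1000); wide$fit_sigma <- 60
  expect_false(any(qc_filter(wide, use_width = TRUE)$passed_qc))
  expect_true(all(qc_filter(wide)$passed_qc))
})
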