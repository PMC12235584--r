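# Grating dispersion calibration, per-localization spectrum extraction,
# Gaussian peak fitting, and the published quality-control filter.

WORKING_RANGE <- c(550, 700) # nm, Nile Red emission window

#' Construct a dispersion calibration from known coefficients
#'
#' Maps spatial-to-spectral pixel distance to emission wavelength in nm
#' through a polynomial `lambda(px) = c0 + c1 px (+ c2 px^2)`.
#'
#' @param coefficients Numeric vector of polynomial coefficients, lowest
#'   order first (length 2 = affine, 3 = quadratic).
#' @param residuals Calibration residuals in nm, if known.
#' @return A `dispersion_cal` object.
#' @export
dispersion_cal <- function(coefficients, residuals = numeric(0)) {
  stopifnot(length(coefficients) %in% c(2, 3))
  cal <- structure(list(coefficients = as.numeric(coefficients),
                        order = length(coefficients) - 1L,
                        residuals = residuals),
                   class = "dispersion_cal")
  .check_monotone(cal)
  cal
}

.lambda_of_px <- function(cal, px) {
  drop(outer(px, seq_along(cal$coefficients) - 1, "^") %*% cal$coefficients)
}

.check_monotone <- function(cal) {
  # require strict monotonicity over the pixel interval mapping onto the
  # Nile Red working range
  px <- .px_grid(cal)
  lam <- .lambda_of_px(cal, px)
  d <- diff(lam)
  if (!(all(d > 0) || all(d < 0)))
    stop("dispersion mapping is not strictly monotone over the 550-700 nm ",
         "working range")
  invisible(TRUE)
}

.px_grid <- function(cal) {
  co <- cal$coefficients
  if (cal$order == 1 || abs(co[3]) < 1e-12) {
    px_ends <- (WORKING_RANGE - co[1]) / co[2]
  } else {
    px_ends <- vapply(WORKING_RANGE, function(lam) {
      disc <- co[2]^2 - 4 * co[3] * (co[1] - lam)
      if (disc < 0)
        stop("dispersion mapping cannot be strictly monotone over the ",
             "550-700 nm working range: it never reaches ", lam, " nm")
      roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
      roots[which.min(abs(roots))]
    }, 0)
  }
  seq(min(px_ends), max(px_ends), length.out = 201)
}

#' Fit a grating dispersion calibration to spectral lamp lines
#'
#' Least-squares polynomial fit of wavelength against spatial-to-spectral
#' pixel distance. With exactly `order + 1` lines the fit interpolates and
#' residuals are identically zero.
#'
#' @param pixel_distance Spatial-to-spectral distances, px.
#' @param wavelength Known line wavelengths, nm (e.g. argon-lamp lines at
#'   435, 586, 763 nm).
#' @param order Polynomial order, 1 (affine) or 2 (default).
#' @return A `dispersion_cal` with per-line residuals (nm).
#' @export
calibrate_dispersion <- function(pixel_distance, wavelength, order = 2) {
  stopifnot(order %in% c(1, 2), length(pixel_distance) == length(wavelength))
  if (length(pixel_distance) < order + 1)
    stop("need at least ", order + 1, " calibration lines for order ", order)
  X <- outer(pixel_distance, 0:order, "^")
  qr_X <- qr(X)
  if (qr_X$rank < order + 1)
    stop("degenerate calibration: pixel distances do not determine a ",
         "unique order-", order, " polynomial")
  beta <- qr.coef(qr_X, wavelength)
  res <- wavelength - drop(X %*% beta)
  dispersion_cal(beta, residuals = res)
}

#' Wavelength at a given spatial-to-spectral pixel distance
#' @param cal A `dispersion_cal`.
#' @param px Pixel distance(s).
#' @return Wavelength(s), nm.
#' @export
wavelength_at <- function(cal, px) .lambda_of_px(cal, px)

#' Pixel distance at which the dispersion reaches a wavelength
#' @param cal A `dispersion_cal`.
#' @param lambda Wavelength(s), nm.
#' @return Pixel distance(s).
#' @export
pixel_at <- function(cal, lambda) {
  co <- cal$coefficients
  if (cal$order == 1 || abs(co[3]) < 1e-12) return((lambda - co[1]) / co[2])
  vapply(lambda, function(lam) {
    disc <- co[2]^2 - 4 * co[3] * (co[1] - lam)
    if (disc < 0) stop("wavelength ", lam, " nm outside dispersion range")
    roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
    grid <- .px_grid(cal)
    inside <- roots >= min(grid) - 1e-9 & roots <= max(grid) + 1e-9
    if (any(inside)) roots[inside][1] else roots[which.min(abs(roots))]
  }, 0)
}

#' Local dispersion slope
#' @param cal A `dispersion_cal`.
#' @param lambda Wavelength at which the slope is evaluated, nm.
#' @return nm of wavelength per pixel, positive.
#' @export
dispersion_slope <- function(cal, lambda = 625) {
  co <- cal$coefficients
  px <- pixel_at(cal, lambda)
  abs(if (cal$order == 1) co[2] else co[2] + 2 * co[3] * px)
}

#' @export
print.dispersion_cal <- function(x, ...) {
  cat(sprintf("Dispersion calibration (order %d): lambda(px) = %s\n",
              x$order,
              paste(sprintf("%.6g px^%d", x$coefficients,
                            seq_along(x$coefficients) - 1), collapse = " + ")))
  if (length(x$residuals))
    cat("  residuals (nm):", paste(sprintf("%.3g", x$residuals),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Extract the emission spectrum of one localization
#'
#' Sums the spectral-channel image over a transverse window of rows centered
#' on the localization, subtracts a per-column background (median over the
#' off-spectrum rows, scaled to the window height), converts pixel distance
#' from the spatial position to wavelength through the calibration, and
#' keeps the samples falling in the 550-700 nm working range.
#'
#' @param loc One-row localization data.frame (needs `x`, `y` in nm and
#'   `frame`).
#' @param spectral_frame Spectral-channel image matrix `[y, x]` for that
#'   frame.
#' @param cal A `dispersion_cal`.
#' @param pixel_size Camera pixel size, nm.
#' @param window Transverse integration window height, px (odd; default 5).
#' @return A `spectral_fit` list with `spectrum` (wavelength nm, intensity),
#'   `photons_spectral`, `off_chip` flag, and empty peak fields.
#' @export
extract_spectrum <- function(loc, spectral_frame, cal, pixel_size,
                             window = 5) {
  stopifnot(window %% 2 == 1, window >= 1)
  n_row <- nrow(spectral_frame); n_col <- ncol(spectral_frame)
  a <- pixel_size
  yc <- ceiling(loc$y / a)
  half <- (window - 1) / 2
  rows <- (yc - half):(yc + half)
  rows <- rows[rows >= 1 & rows <= n_row]
  off_rows <- setdiff(seq_len(n_row), (yc - 3 * half):(yc + 3 * half))
  if (length(off_rows) < 5) off_rows <- setdiff(seq_len(n_row), rows)
  bg_col <- apply(spectral_frame[off_rows, , drop = FALSE], 2, stats::median)
  profile <- colSums(spectral_frame[rows, , drop = FALSE]) -
    length(rows) * bg_col
  # pixel-center distances from the spatial-channel position
  px_centers <- (seq_len(n_col) - 0.5)
  dpx <- px_centers - loc$x / a
  lam <- wavelength_at(cal, dpx)
  keep <- lam >= WORKING_RANGE[1] & lam <= WORKING_RANGE[2]
  # the full working range must fit on the chip
  px_need <- pixel_at(cal, WORKING_RANGE) + loc$x / a
  off_chip <- min(px_need) < 0 || max(px_need) > n_col
  spec <- data.frame(wavelength = lam[keep], intensity = profile[keep])
  spec <- spec[order(spec$wavelength), ]
  structure(list(frame = loc$frame, x = loc$x, y = loc$y,
                 spectrum = spec,
                 photons_spectral = sum(spec$intensity),
                 off_chip = off_chip,
                 peak_wavelength = NA_real_, centroid_wavelength = NA_real_,
                 peak_uncertainty = NA_real_, fit_sigma = NA_real_,
                 passed_qc = NA, qc_reason = NA_character_),
            class = "spectral_fit")
}

#' Gaussian peak fit of an extracted spectrum
#'
#' Least-squares 1D Gaussian fit of intensity against wavelength
#' (Levenberg-Marquardt); the peak wavelength is the fitted center and the
#' peak uncertainty its standard error. The centroid wavelength is the
#' intensity-weighted mean (negative intensities clipped to zero for the
#' weights).
#'
#' @param sf A `spectral_fit` from [extract_spectrum()].
#' @return `sf` with `peak_wavelength`, `peak_uncertainty`, `fit_sigma`,
#'   `centroid_wavelength` filled; on non-convergence `passed_qc` is set
#'   `FALSE` with a reason.
#' @export
fit_peak <- function(sf) {
  stopifnot(inherits(sf, "spectral_fit"))
  spec <- sf$spectrum
  if (nrow(spec) < 4 || all(spec$intensity <= 0)) {
    sf$passed_qc <- FALSE
    sf$qc_reason <- "empty or non-positive spectrum"
    return(sf)
  }
  w <- pmax(spec$intensity, 0)
  sf$centroid_wavelength <- sum(spec$wavelength * w) / sum(w)
  i0 <- which.max(spec$intensity)
  start <- list(A = spec$intensity[i0], mu = spec$wavelength[i0], s = 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ A * exp(-(wavelength - mu)^2 / (2 * s^2)),
                      data = spec, start = start,
                      lower = c(0, WORKING_RANGE[1] - 50, 1),
                      upper = c(Inf, WORKING_RANGE[2] + 50, 200),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    sf$passed_qc <- FALSE
    sf$qc_reason <- "peak fit did not converge"
    return(sf)
  }
  est <- summary(fit)$coefficients
  sf$peak_wavelength <- est["mu", "Estimate"]
  sf$peak_uncertainty <- est["mu", "Std. Error"]
  sf$fit_sigma <- est["s", "Estimate"]
  sf
}

#' Extract and fit spectra for a localization table
#'
#' Runs [extract_spectrum()] and [fit_peak()] for every localization against
#' the matching spectral frame and returns one row per localization.
#'
#' @param locs Localization data.frame (`frame`, `x`, `y` in nm; an
#'   `intensity` column, if present, is carried as `photons_spatial`).
#' @param spectral_stack Spectral-channel array `[y, x, frame]`.
#' @param cal A `dispersion_cal`.
#' @param pixel_size Pixel size, nm.
#' @param window Transverse window, px.
#' @return A `spectral_fits` data.frame: `loc_id`, `frame`, `x`, `y`,
#'   `peak_wavelength`, `centroid_wavelength`, `fit_sigma`,
#'   `peak_uncertainty`, `photons_spatial`, `photons_spectral`, `off_chip`,
#'   `passed_qc`, `qc_reason`.
#' @export
spaint_spectra <- function(locs, spectral_stack, cal, pixel_size,
                           window = 5) {
  n <- nrow(locs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sf <- extract_spectrum(locs[i, ], spectral_stack[, , locs$frame[i]],
                           cal, pixel_size, window)
    sf <- fit_peak(sf)
    rows[[i]] <- data.frame(
      loc_id = i, frame = locs$frame[i], x = locs$x[i], y = locs$y[i],
      peak_wavelength = sf$peak_wavelength,
      centroid_wavelength = sf$centroid_wavelength,
      fit_sigma = sf$fit_sigma, peak_uncertainty = sf$peak_uncertainty,
      photons_spatial = if ("intensity" %in% names(locs))
        locs$intensity[i] else NA_real_,
      photons_spectral = sf$photons_spectral,
      off_chip = sf$off_chip,
      passed_qc = sf$passed_qc,
      qc_reason = sf$qc_reason, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("spectral_fits", "data.frame")
  out
}

#' Apply the published spectral quality-control filter
#'
#' A fit passes when its peak uncertainty does not exceed `max_uncertainty`
#' AND its spectral photon count is at least `min_photons`; the printed
#' rules ">40 nm" and "<300 photons" are read literally, so records exactly
#' at 40 nm or 300 photons survive. Off-chip or failed fits never pass.
#' Wavelength values are never altered.
#'
#' @param fits A `spectral_fits` data.frame.
#' @param max_uncertainty Rejection threshold on the peak-center standard
#'   error, nm (default 40). Set `use_width = TRUE` to filter on the fitted
#'   Gaussian width instead.
#' @param min_photons Minimum spectral photons (default 300).
#' @param use_width Filter on `fit_sigma` rather than `peak_uncertainty`.
#' @return `fits` with `passed_qc` and `qc_reason` set.
#' @export
qc_filter <- function(fits, max_uncertainty = 40, min_photons = 300,
                      use_width = FALSE) {
  unc <- if (use_width) fits$fit_sigma else fits$peak_uncertainty
  failed_fit <- !is.na(fits$passed_qc) & !fits$passed_qc
  ok_unc <- !is.na(unc) & unc <= max_uncertainty
  ok_ph <- !is.na(fits$photons_spectral) & fits$photons_spectral >= min_photons
  ok_chip <- !fits$off_chip
  pass <- ok_unc & ok_ph & ok_chip & !failed_fit
  reason <- rep(NA_character_, nrow(fits))
  reason[!ok_unc] <- sprintf("uncertainty > %g nm", max_uncertainty)
  reason[!ok_ph] <- sprintf("spectral photons < %g", min_photons)
  reason[!ok_chip] <- "spectrum support off chip"
  reason[failed_fit] <- fits$qc_reason[failed_fit]
  fits$passed_qc <- pass
  fits$qc_reason <- reason
  fits
}

#' Keep only QC-passing spectral fits
#' @param fits A `spectral_fits` data.frame with `passed_qc` set.
#' @return The passing subset.
#' @export
qc_pass <- function(fits) {
  if (anyNA(fits$passed_qc)) stop("run qc_filter() first")
  fits[fits$passed_qc, , drop = FALSE]
}
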