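# Ground-truthed synthetic data: blinking Nile Red binding events on
# nanoparticles, rendered into paired spatial + spectral camera stacks, plus
# TEM-like size distributions and Brownian bilayer head-group trajectories.

#' Simulation configuration for synthetic sPAINT movies
#'
#' @param fov_px Square field of view, pixels.
#' @param pixel_size Camera pixel size in nm (90 on the spectral rig; the
#'   colocalization rig uses 117).
#' @param n_frames Number of frames.
#' @param exposure Exposure time per frame, ms.
#' @param psf_sigma Gaussian PSF sigma, nm.
#' @param photons_mean Mean emitted photons per bright frame (before the
#'   grating split).
#' @param zeroth_fraction,first_fraction Fraction of emitted photons reaching
#'   the zeroth-order (spatial) and first-order (spectral) images; grating
#'   manufacturer values 0.41 and 0.32.
#' @param background_rate Mean background, counts per pixel per frame.
#' @param dispersion A [dispersion_cal()] mapping spatial-to-spectral pixel
#'   distance to wavelength (default affine, 3.2 nm/px with 450 nm offset).
#' @param spectral_fwhm Emission footprint FWHM in wavelength units, nm.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fov_px = 192, pixel_size = 90, n_frames = 1500,
                       exposure = 50, psf_sigma = 130, photons_mean = 2000,
                       zeroth_fraction = 0.41, first_fraction = 0.32,
                       background_rate = 2,
                       dispersion = dispersion_cal(c(450, 3.2)),
                       spectral_fwhm = 45, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(fov_px > 0, pixel_size > 0, n_frames > 0, exposure > 0,
            psf_sigma > 0, photons_mean > 0,
            zeroth_fraction > 0, first_fraction > 0,
            zeroth_fraction + first_fraction <= 1,
            background_rate >= 0, spectral_fwhm > 0)
  structure(list(fov_px = as.integer(fov_px), pixel_size = pixel_size,
                 n_frames = as.integer(n_frames), exposure = exposure,
                 psf_sigma = psf_sigma, photons_mean = photons_mean,
                 zeroth_fraction = zeroth_fraction,
                 first_fraction = first_fraction,
                 background_rate = background_rate, dispersion = dispersion,
                 spectral_fwhm = spectral_fwhm, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a field of ground-truth particles
#'
#' Particle centers are drawn uniformly in the left portion of the field of
#' view (leaving room for the first-order spectral footprint to the right)
#' with a minimum pairwise spacing; each particle carries its own mean
#' emission peak wavelength, intra-particle wavelength spread, and blinking
#' rates.
#'
#' @param n Number of particles.
#' @param config A [sim_config()].
#' @param wavelength_mean Mean peak wavelength per particle, nm; recycled.
#'   Must lie in the Nile Red emission range 550-700 nm.
#' @param wavelength_sd Intra-particle wavelength sd, nm; recycled.
#' @param diameter_mean,diameter_sd Particle diameter distribution, nm
#'   (truncated at 20 nm).
#' @param on_rate,off_rate Per-frame dark->bright and bright->dark
#'   probabilities.
#' @param coated Logical, recycled; uncoated particles bind no dye.
#' @param min_spacing Minimum center-to-center distance, nm.
#' @param region_frac_x Particles are placed within this left fraction of
#'   the FOV width.
#' @param margin_px Border margin, pixels.
#' @return A `data.frame` of ground-truth particles.
#' @export
particle_field <- function(n, config, wavelength_mean = 610,
                           wavelength_sd = 4, diameter_mean = 80,
                           diameter_sd = 12, on_rate = 0.06, off_rate = 0.85,
                           coated = TRUE, min_spacing = 800,
                           region_frac_x = 0.35, margin_px = 8) {
  stopifnot(n >= 1, all(wavelength_mean >= 550), all(wavelength_mean <= 700),
            all(on_rate > 0), all(on_rate <= 1),
            all(off_rate > 0), all(off_rate <= 1))
  set.seed(config$seed)
  a <- config$pixel_size
  xmax <- (config$fov_px * region_frac_x - margin_px) * a
  ymax <- (config$fov_px - margin_px) * a
  xmin <- margin_px * a
  xy <- matrix(NA_real_, n, 2)
  placed <- 0
  for (attempt in seq_len(n * 2000)) {
    cand <- c(stats::runif(1, xmin, xmax), stats::runif(1, xmin, ymax))
    if (placed == 0 ||
        min(sqrt(colSums((t(xy[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
        min_spacing) {
      placed <- placed + 1
      xy[placed, ] <- cand
      if (placed == n) break
    }
  }
  if (placed < n) stop("could not place ", n, " particles with spacing ",
                       min_spacing, " nm; enlarge FOV or lower spacing")
  d <- stats::rnorm(n, diameter_mean, diameter_sd)
  d[d < 20] <- 20
  data.frame(id = seq_len(n), x = xy[, 1], y = xy[, 2], diameter = d,
             coated = rep_len(coated, n),
             peak_wavelength_mean = rep_len(wavelength_mean, n),
             peak_wavelength_sd = rep_len(wavelength_sd, n),
             on_rate = rep_len(on_rate, n), off_rate = rep_len(off_rate, n))
}

#' Simulate transient-binding blinking events
#'
#' Each coated particle follows an independent two-state (dark/bright)
#' frame-level Markov chain: dark->bright with probability `on_rate`,
#' bright->dark with `off_rate`, started from the stationary distribution,
#' so bright stretches are geometric with mean `1/off_rate` frames. Each
#' bright frame emits Poisson photons around the configured mean, at a
#' position drawn uniformly on the particle's projected disc, with a peak
#' wavelength drawn from the particle's Normal(mean, sd).
#'
#' @param particles A [particle_field()] data.frame.
#' @param config A [sim_config()].
#' @return A `data.frame` of events: `frame`, `particle`, `x`, `y` (nm),
#'   `photons` (emitted, pre-split), `wavelength` (nm).
#' @export
simulate_blinking <- function(particles, config) {
  force(particles)  # must evaluate before seeding: it may consume the RNG
  set.seed(config$seed + 1L)
  nf <- config$n_frames
  ev <- vector("list", nrow(particles))
  for (i in seq_len(nrow(particles))) {
    p <- particles[i, ]
    if (!p$coated) next
    pon <- p$on_rate; poff <- p$off_rate
    state <- stats::runif(1) < pon / (pon + poff)
    bright <- logical(nf)
    u <- stats::runif(nf)
    for (t in seq_len(nf)) {
      state <- if (state) u[t] >= poff else u[t] < pon
      bright[t] <- state
    }
    frames <- which(bright)
    if (length(frames) == 0) next
    k <- length(frames)
    # binding position uniform on the projected disc
    rr <- (p$diameter / 2) * sqrt(stats::runif(k))
    th <- stats::runif(k, 0, 2 * pi)
    ev[[i]] <- data.frame(
      frame = frames, particle = p$id,
      x = p$x + rr * cos(th), y = p$y + rr * sin(th),
      photons = stats::rpois(k, config$photons_mean),
      wavelength = stats::rnorm(k, p$peak_wavelength_mean,
                                p$peak_wavelength_sd))
  }
  out <- do.call(rbind, ev)
  if (is.null(out))
    out <- data.frame(frame = integer(), particle = integer(), x = numeric(),
                      y = numeric(), photons = numeric(),
                      wavelength = numeric())
  out <- out[order(out$frame, out$particle), ]
  rownames(out) <- NULL
  out
}

# integrated (pixel-binned) Gaussian profile over pixel index range
.pix_gauss <- function(lo_px, hi_px, center_nm, sigma_nm, a) {
  edges <- (lo_px - 1):hi_px * a
  diff(stats::pnorm(edges, center_nm, sigma_nm))
}

#' Render paired spatial and spectral camera stacks
#'
#' The spatial (zeroth-order) channel receives an integrated 2D Gaussian PSF
#' at each event position carrying `zeroth_fraction` of the event's photons.
#' The spectral (first-order) channel receives a footprint displaced along
#' +x by the grating dispersion evaluated at the event wavelength: Gaussian
#' in wavelength (configured FWHM, converted to chip distance through the
#' local dispersion) and PSF-sized transversally, carrying `first_fraction`
#' of the photons. Poisson shot noise and a uniform Poisson background are
#' added unless `noise = FALSE`. Events whose footprint center would fall
#' off-chip are dropped and logged in the truth table.
#'
#' @param events Event table from [simulate_blinking()].
#' @param config A [sim_config()].
#' @param noise Add Poisson noise and background? Default `TRUE`.
#' @return A `spaint_movie` list: `spatial` and `spectral` arrays
#'   `[y, x, frame]`, and `truth` (one row per event with `dropped` flag).
#' @export
render_movie <- function(events, config, noise = TRUE) {
  force(events)  # must evaluate before seeding: it may consume the RNG
  set.seed(config$seed + 2L)
  n <- config$fov_px; a <- config$pixel_size; nf <- config$n_frames
  spatial <- array(0, c(n, n, nf))
  spectral <- array(0, c(n, n, nf))
  sig <- config$psf_sigma
  slope <- dispersion_slope(config$dispersion, 625) # nm wavelength per px
  sig_spec_nm <- config$spectral_fwhm / (2 * sqrt(2 * log(2))) / slope * a
  half_sp <- ceiling(6 * sig / a) + 1L
  half_sx <- ceiling(6 * sig_spec_nm / a) + 1L
  dropped <- logical(nrow(events))
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    fr <- e$frame
    cx <- e$x / a; cy <- e$y / a   # continuous px
    # spatial channel
    ix <- max(1L, floor(cx) - half_sp):min(n, ceiling(cx) + half_sp)
    iy <- max(1L, floor(cy) - half_sp):min(n, ceiling(cy) + half_sp)
    if (length(ix) && length(iy)) {
      gx <- .pix_gauss(ix[1], ix[length(ix)], e$x, sig, a)
      gy <- .pix_gauss(iy[1], iy[length(iy)], e$y, sig, a)
      spatial[iy, ix, fr] <- spatial[iy, ix, fr] +
        e$photons * config$zeroth_fraction * (gy %o% gx)
    }
    # spectral channel
    dx_px <- pixel_at(config$dispersion, e$wavelength)
    sx <- e$x + dx_px * a
    if (sx / a > n - 1 || sx / a < 1) { dropped[k] <- TRUE; next }
    jx <- max(1L, floor(sx / a) - half_sx):min(n, ceiling(sx / a) + half_sx)
    jy <- max(1L, floor(cy) - half_sp):min(n, ceiling(cy) + half_sp)
    if (length(jx) && length(jy)) {
      gx <- .pix_gauss(jx[1], jx[length(jx)], sx, sig_spec_nm, a)
      gy <- .pix_gauss(jy[1], jy[length(jy)], e$y, sig, a)
      spectral[jy, jx, fr] <- spectral[jy, jx, fr] +
        e$photons * config$first_fraction * (gy %o% gx)
    }
  }
  if (noise) {
    npx <- n * n
    for (fr in seq_len(nf)) {  # frame-wise to bound peak memory
      spatial[, , fr] <- stats::rpois(npx,
                                      spatial[, , fr] + config$background_rate)
      spectral[, , fr] <- stats::rpois(npx,
                                       spectral[, , fr] + config$background_rate)
    }
  }
  truth <- events
  truth$dropped <- dropped
  structure(list(spatial = spatial, spectral = spectral, truth = truth),
            class = "spaint_movie")
}

#' Write a movie stack as multi-page TIFF
#'
#' @param stack 3D array `[y, x, frame]`.
#' @param path Output file.
#' @param scale Counts are divided by this before writing (TIFF stores
#'   [0, 1] floats); default 65535.
#' @export
write_movie_tiff <- function(stack, path, scale = 65535) {
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a movie stack
#'
#' @param path TIFF file.
#' @param scale Multiplier restoring counts (matches [write_movie_tiff()]).
#' @return 3D array `[y, x, frame]`.
#' @export
read_movie_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  array(unlist(pages), c(dim(pages[[1]]), length(pages))) * scale
}

#' Simulate a TEM-like nanocapsule size distribution
#'
#' Truncated-normal diameter draws binned on a uniform 5 nm grid;
#' frequencies are percentages summing to exactly 100.
#'
#' @param mean,sd Underlying normal parameters, nm.
#' @param n Number of simulated capsules.
#' @param seed Integer seed.
#' @param support Truncation interval, nm.
#' @param bin_width Bin width, nm.
#' @return A `size_distribution` data.frame (as
#'   [size_distribution_truncnorm()]) with attribute `diameters` holding the
#'   raw draws.
#' @export
simulate_size_distribution <- function(mean = 79.4, sd = 11.6, n = 1e4, seed,
                                       support = c(45, 125), bin_width = 5) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n >= 1)
  set.seed(seed)
  if (sd <= 0) {
    d <- rep(mean, n)
  } else {
    lo <- stats::pnorm(support[1], mean, sd)
    hi <- stats::pnorm(support[2], mean, sd)
    d <- stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  }
  edges <- seq(support[1], support[2], by = bin_width)
  cnt <- graphics::hist(d, breaks = edges, plot = FALSE)$counts
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    diameter_mid = edges[-length(edges)] + bin_width / 2,
                    frequency = 100 * cnt / sum(cnt))
  attr(out, "diameters") <- d
  class(out) <- c("size_distribution", "data.frame")
  out
}

#' Simulate a bilayer head-group trajectory
#'
#' 2D Brownian motion of lipid phosphate head groups with per-axis step
#' variance 2 D dt, wrapped into a square periodic box whose area fluctuates
#' as a Gaussian around `n_per_leaflet * apl_mean`; leaflet z levels sit at
#' +/- d_hh/2 with small Gaussian roughness.
#'
#' @param n_heads Total head groups (both leaflets; must be even).
#' @param D_true Lateral diffusion coefficient, um^2/s.
#' @param apl_mean,apl_sd Area per lipid mean and sd, nm^2.
#' @param d_hh Head-to-head bilayer thickness, nm.
#' @param n_steps Stored time steps.
#' @param dt Time step, ns.
#' @param seed Integer seed.
#' @param z_sigma Leaflet roughness sd, nm.
#' @param temperature Kelvin, carried for the compressibility estimator.
#' @return A `head_trajectory` object: `times` (ns), `Lx`, `Ly` (nm,
#'   per-time), matrices `x`, `y`, `z` of dim `[n_steps, n_heads]` (wrapped
#'   coordinates), `leaflet`, `n_per_leaflet`, `temperature`.
#' @export
simulate_trajectory <- function(n_heads = 1000, D_true = 5, apl_mean = 0.42,
                                apl_sd = 0.004, d_hh = 4.0, n_steps = 1e4,
                                dt = 2, seed, z_sigma = 0.3,
                                temperature = 310) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_heads >= 2, n_heads %% 2 == 0, D_true >= 0, apl_mean > 0,
            apl_sd >= 0, d_hh > 0, n_steps >= 2, dt > 0)
  set.seed(seed)
  npl <- n_heads %/% 2
  area <- npl * (apl_mean + stats::rnorm(n_steps, 0, apl_sd))
  if (any(area <= 0)) stop("box area fluctuated non-positive; lower apl_sd")
  L <- sqrt(area)
  step_sd <- sqrt(2 * D_true * 1e-3 * dt)  # um^2/s -> nm^2/ns conversion
  x <- matrix(0, n_steps, n_heads)
  y <- matrix(0, n_steps, n_heads)
  x[1, ] <- stats::runif(n_heads, 0, L[1])
  y[1, ] <- stats::runif(n_heads, 0, L[1])
  if (step_sd > 0) {
    dx <- matrix(stats::rnorm((n_steps - 1) * n_heads, 0, step_sd),
                 n_steps - 1, n_heads)
    dy <- matrix(stats::rnorm((n_steps - 1) * n_heads, 0, step_sd),
                 n_steps - 1, n_heads)
    for (t in 2:n_steps) {
      x[t, ] <- (x[t - 1, ] + dx[t - 1, ]) %% L[t]
      y[t, ] <- (y[t - 1, ] + dy[t - 1, ]) %% L[t]
    }
  } else {
    for (t in 2:n_steps) { x[t, ] <- x[1, ]; y[t, ] <- y[1, ] }
  }
  leaflet <- rep(c("upper", "lower"), each = npl)
  zlev <- ifelse(leaflet == "upper", d_hh / 2, -d_hh / 2)
  z <- matrix(rep(zlev, each = n_steps), n_steps, n_heads) +
    matrix(stats::rnorm(n_steps * n_heads, 0, z_sigma), n_steps, n_heads)
  structure(list(times = (seq_len(n_steps) - 1) * dt, Lx = L, Ly = L,
                 x = x, y = y, z = z, leaflet = leaflet,
                 n_per_leaflet = npl, temperature = temperature,
                 D_true = D_true),
            class = "head_trajectory")
}

#' @export
print.head_trajectory <- function(x, ...) {
  cat(sprintf(
    "Head-group trajectory: %d heads (%d per leaflet), %d steps, %.3g ns span\n",
    ncol(x$x), x$n_per_leaflet, nrow(x$x), max(x$times)))
  cat(sprintf("  mean box %.2f x %.2f nm, T = %g K\n",
              mean(x$Lx), mean(x$Ly), x$temperature))
  invisible(x)
}

#' Write a head trajectory to long-format CSV
#'
#' Columns: `time_ns, Lx_nm, Ly_nm, id, leaflet, x_nm, y_nm, z_nm`.
#'
#' @param traj A `head_trajectory`.
#' @param path Output CSV.
#' @param every Keep every k-th stored step (thins large trajectories).
#' @export
write_trajectory <- function(traj, path, every = 1) {
  keep <- seq(1, nrow(traj$x), by = every)
  nh <- ncol(traj$x)
  df <- data.frame(
    time_ns = rep(traj$times[keep], each = nh),
    Lx_nm = rep(traj$Lx[keep], each = nh),
    Ly_nm = rep(traj$Ly[keep], each = nh),
    id = rep(seq_len(nh), times = length(keep)),
    leaflet = rep(traj$leaflet, times = length(keep)),
    x_nm = as.vector(t(traj$x[keep, , drop = FALSE])),
    y_nm = as.vector(t(traj$y[keep, , drop = FALSE])),
    z_nm = as.vector(t(traj$z[keep, , drop = FALSE])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a head trajectory from long-format CSV
#'
#' @param path CSV written by [write_trajectory()] (or equivalent).
#' @param n_per_leaflet Heads per leaflet; inferred from leaflet tags if
#'   missing.
#' @param temperature Kelvin.
#' @return A `head_trajectory` object.
#' @export
read_trajectory <- function(path, n_per_leaflet = NULL, temperature = 310) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ns", "Lx_nm", "Ly_nm", "id", "leaflet",
            "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  times <- sort(unique(df$time_ns))
  ids <- sort(unique(df$id))
  df <- df[order(df$time_ns, df$id), ]
  nt <- length(times); nh <- length(ids)
  if (nrow(df) != nt * nh) stop("trajectory table is ragged")
  shape <- function(v) matrix(v, nt, nh, byrow = TRUE)
  leaflet <- df$leaflet[seq_len(nh)]
  if (is.null(n_per_leaflet)) n_per_leaflet <- sum(leaflet == leaflet[1])
  structure(list(times = times,
                 Lx = df$Lx_nm[seq(1, nrow(df), by = nh)],
                 Ly = df$Ly_nm[seq(1, nrow(df), by = nh)],
                 x = shape(df$x_nm), y = shape(df$y_nm), z = shape(df$z_nm),
                 leaflet = leaflet, n_per_leaflet = n_per_leaflet,
                 temperature = temperature),
            class = "head_trajectory")
}
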