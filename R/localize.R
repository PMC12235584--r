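# Spatial-channel single-molecule detection and Gaussian fitting, drift
# correction by redundant cross-correlation, density filtering, and
# core/coating colocalization.

#' Detect and fit single-molecule events in a movie stack
#'
#' Candidate emitters are local maxima above a robust per-frame threshold
#' (median + k MAD). Each candidate is refined by least-squares fitting of a
#' pixel-integrated symmetric 2D Gaussian with constant offset over a square
#' window, giving sub-pixel positions in nm, total photons, background
#' offset, and a Thompson-style localization precision.
#'
#' @param stack 3D array `[y, x, frame]` of camera counts.
#' @param pixel_size Pixel size, nm.
#' @param threshold_k Threshold in MADs above the median of the
#'   PSF-smoothed frame (default 5).
#' @param fit_window Square fit window side, px (odd, default 7).
#' @param psf_sigma_guess Starting PSF sigma for the fit, nm (default 150);
#'   also sets the matched smoothing kernel.
#' @return A `localizations` data.frame: `frame`, `x`, `y` (nm), `sigma`
#'   (nm), `intensity` (photons), `offset` (counts/px), `uncertainty_xy`
#'   (nm). The number of dropped (non-converged) fits is stored in
#'   `attr(, "n_dropped")`.
#' @export
detect_and_fit <- function(stack, pixel_size, threshold_k = 5,
                           fit_window = 7, psf_sigma_guess = 150) {
  stopifnot(length(dim(stack)) == 3, fit_window %% 2 == 1)
  half <- (fit_window - 1) / 2
  n_row <- dim(stack)[1]; n_col <- dim(stack)[2]; nf <- dim(stack)[3]
  sig_px <- psf_sigma_guess / pixel_size
  Ky <- .gauss_band(n_row, sig_px)
  Kx <- t(.gauss_band(n_col, sig_px))
  out <- vector("list", nf)
  n_dropped <- 0L
  for (fr in seq_len(nf)) {
    img <- stack[, , fr]
    sm <- Ky %*% img %*% Kx   # matched-filter smoothing kills shot noise
    med <- stats::median(sm)
    thr <- med + threshold_k * stats::mad(sm)
    peaks <- .local_maxima(sm, thr)
    if (nrow(peaks) == 0) next
    keep <- peaks[, 1] > half & peaks[, 1] <= n_row - half &
      peaks[, 2] > half & peaks[, 2] <= n_col - half
    peaks <- peaks[keep, , drop = FALSE]
    if (nrow(peaks) == 0) next
    recs <- vector("list", nrow(peaks))
    for (k in seq_len(nrow(peaks))) {
      fit <- .fit_gaussian_2d(img, peaks[k, 1], peaks[k, 2], half,
                              pixel_size, psf_sigma_guess)
      if (is.null(fit)) { n_dropped <- n_dropped + 1L; next }
      recs[[k]] <- cbind(frame = fr, fit)
    }
    out[[fr]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      sigma = numeric(), intensity = numeric(),
                      offset = numeric(), uncertainty_xy = numeric())
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_dropped
  attr(res, "pixel_size") <- pixel_size
  class(res) <- c("localizations", "data.frame")
  res
}

# row-normalized Gaussian smoothing band matrix (replicated edges absorb
# the truncated tails)
.gauss_band <- function(n, sigma_px) {
  h <- max(1L, ceiling(3 * sigma_px))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) stats::dnorm(j - i, 0, sigma_px))
  K[abs(row(K) - col(K)) > h] <- 0
  K / rowSums(K)
}

# 8-neighborhood local maxima above a threshold; returns cbind(row, col)
.local_maxima <- function(img, thr) {
  n_row <- nrow(img); n_col <- ncol(img)
  pad <- matrix(-Inf, n_row + 2, n_col + 2)
  pad[2:(n_row + 1), 2:(n_col + 1)] <- img
  ctr <- pad[2:(n_row + 1), 2:(n_col + 1)]
  is_max <- ctr > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[2:(n_row + 1) + dy, 2:(n_col + 1) + dx]
    is_max <- is_max & (ctr >= nb)
  }
  which(is_max, arr.ind = TRUE)
}

# pixel-integrated symmetric 2D Gaussian + offset LS fit on a window
.fit_gaussian_2d <- function(img, row0, col0, half, a, sigma_guess) {
  rows <- (row0 - half):(row0 + half)
  cols <- (col0 - half):(col0 + half)
  patch <- img[rows, cols]
  z <- as.vector(patch)
  df <- data.frame(
    z = z,
    cx = rep((cols - 0.5) * a, each = length(rows)),
    cy = rep((rows - 0.5) * a, times = length(cols)),
    xlo = rep((cols - 1) * a, each = length(rows)),
    ylo = rep((rows - 1) * a, times = length(cols)))
  b0 <- min(z)
  n0 <- max(sum(z - b0), 1)
  x0 <- sum(df$cx * pmax(z - b0, 0)) / max(sum(pmax(z - b0, 0)), 1e-9)
  y0 <- sum(df$cy * pmax(z - b0, 0)) / max(sum(pmax(z - b0, 0)), 1e-9)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ N * (pnorm(xlo + a, x0f, s) - pnorm(xlo, x0f, s)) *
        (pnorm(ylo + a, y0f, s) - pnorm(ylo, y0f, s)) + b,
      data = cbind(df, a = a),
      start = list(N = n0, x0f = x0, y0f = y0, s = sigma_guess, b = b0),
      lower = c(1, min(df$xlo), min(df$ylo), a / 4, 0),
      upper = c(Inf, max(df$xlo) + a, max(df$ylo) + a, 10 * sigma_guess, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 60)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  if (p[["N"]] <= 0 || p[["s"]] <= 0) return(NULL)
  prec <- thompson_precision(p[["s"]], a, p[["N"]], p[["b"]])
  data.frame(x = p[["x0f"]], y = p[["y0f"]], sigma = p[["s"]],
             intensity = p[["N"]], offset = p[["b"]],
             uncertainty_xy = prec)
}

#' Localization precision for least-squares Gaussian fitting
#'
#' Thompson-style shot-noise formula with the least-squares correction:
#' `sigma_loc^2 = (s_a^2 / N) (16/9 + 8 pi s_a^2 b^2 / (N a^2))` where
#' `s_a^2 = s^2 + a^2/12` is the pixelation-corrected PSF variance, `N` the
#' photon count, `a` the pixel size and `b^2` the per-pixel background
#' variance (equal to the offset level for Poisson background).
#'
#' @param s PSF sigma, nm.
#' @param a Pixel size, nm.
#' @param N Photons.
#' @param b_level Background level, counts/px (its Poisson variance is used).
#' @return Precision (1 sd per axis) in nm.
#' @export
thompson_precision <- function(s, a, N, b_level) {
  b2 <- pmax(b_level, 0)  # Poisson variance equals the level
  sa2 <- s^2 + a^2 / 12
  sqrt((sa2 / N) * (16 / 9 + 8 * pi * sa2 * b2 / (N * a^2)))
}

#' Drift correction by redundant cross-correlation
#'
#' Localizations are split into temporal bins; each bin is rendered as a 2D
#' histogram image at `render_px` resolution and all bin pairs are
#' cross-correlated by FFT with parabolic sub-pixel peak refinement. The
#' redundant pairwise shift measurements are reduced to per-bin drifts by
#' least squares (first bin fixed at zero), interpolated to every frame with
#' a natural cubic spline, and subtracted. Relative positions within a frame
#' are preserved exactly.
#'
#' @param locs A `localizations` data.frame.
#' @param n_bins Number of temporal bins (default 10).
#' @param render_px Super-resolved render pixel, nm (default 30).
#' @return List with `locs` (corrected), `drift` (data.frame `frame`, `dx`,
#'   `dy` in nm), `applied` (logical).
#' @export
drift_correct <- function(locs, n_bins = 10, render_px = 30) {
  if (nrow(locs) == 0) return(list(locs = locs, drift = NULL, applied = FALSE))
  frames <- range(locs$frame)
  if (n_bins < 2) {
    warning("drift correction needs >= 2 temporal bins; returning identity")
    drift <- data.frame(frame = seq(frames[1], frames[2]), dx = 0, dy = 0)
    return(list(locs = locs, drift = drift, applied = FALSE))
  }
  edges <- seq(frames[1] - 0.5, frames[2] + 0.5, length.out = n_bins + 1)
  bin_of <- cut(locs$frame, edges, labels = FALSE)
  counts <- tabulate(bin_of, n_bins)
  if (any(counts < 10)) {
    warning("insufficient localizations per temporal bin; returning identity")
    drift <- data.frame(frame = seq(frames[1], frames[2]), dx = 0, dy = 0)
    return(list(locs = locs, drift = drift, applied = FALSE))
  }
  xr <- range(locs$x); yr <- range(locs$y)
  nx <- max(16, 2^ceiling(log2((xr[2] - xr[1]) / render_px + 2)))
  ny <- max(16, 2^ceiling(log2((yr[2] - yr[1]) / render_px + 2)))
  render <- function(sel) {
    ix <- pmin(pmax(floor((locs$x[sel] - xr[1]) / render_px) + 1, 1), nx)
    iy <- pmin(pmax(floor((locs$y[sel] - yr[1]) / render_px) + 1, 1), ny)
    m <- matrix(0, ny, nx)
    tab <- table(iy, ix)
    m[cbind(as.integer(rownames(tab))[row(tab)],
            as.integer(colnames(tab))[col(tab)])] <- as.vector(tab)
    m
  }
  imgs <- lapply(seq_len(n_bins), function(b) render(bin_of == b))
  ffts <- lapply(imgs, stats::fft)
  pairs <- utils::combn(n_bins, 2)
  shifts <- matrix(0, ncol(pairs), 2)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    xc <- Re(stats::fft(ffts[[j]] * Conj(ffts[[i]]), inverse = TRUE))
    shifts[p, ] <- .cc_peak_shift(xc) * render_px   # shift of j relative to i
  }
  # least squares: s_j - s_i = measured, s_1 = 0
  A <- matrix(0, ncol(pairs), n_bins - 1)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (j > 1) A[p, j - 1] <- 1
    if (i > 1) A[p, i - 1] <- -1
  }
  sx <- c(0, stats::lm.fit(A, shifts[, 1])$coefficients)
  sy <- c(0, stats::lm.fit(A, shifts[, 2])$coefficients)
  bin_centers <- (edges[-1] + edges[-length(edges)]) / 2
  all_frames <- seq(frames[1], frames[2])
  fx <- stats::spline(bin_centers, sx, xout = all_frames, method = "natural")$y
  fy <- stats::spline(bin_centers, sy, xout = all_frames, method = "natural")$y
  drift <- data.frame(frame = all_frames, dx = fx, dy = fy)
  idx <- match(locs$frame, all_frames)
  locs$x <- locs$x - drift$dx[idx]
  locs$y <- locs$y - drift$dy[idx]
  list(locs = locs, drift = drift, applied = TRUE)
}

# sub-pixel peak of a circular cross-correlation surface
.cc_peak_shift <- function(xc) {
  ny <- nrow(xc); nx <- ncol(xc)
  pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ((i - 1 + n / 2) %% n) - n / 2
  # parabolic refinement along each axis (circular indexing)
  at <- function(r, c) xc[(r - 1) %% ny + 1, (c - 1) %% nx + 1]
  refine <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (den == 0) 0 else 0.5 * (m1 - p1) / den
  }
  dyy <- refine(at(pk[1] - 1, pk[2]), at(pk[1], pk[2]), at(pk[1] + 1, pk[2]))
  dxx <- refine(at(pk[1], pk[2] - 1), at(pk[1], pk[2]), at(pk[1], pk[2] + 1))
  c(wrap(pk[2], nx) + dxx, wrap(pk[1], ny) + dyy)  # (x, y)
}

#' Density filter
#'
#' Keeps localizations having at least `min_neighbors` other localizations
#' (any frame) within `radius`. Idempotent at a fixed point; output is
#' always a subset of the input.
#'
#' @param locs A `localizations` data.frame.
#' @param radius Neighborhood radius, nm (default 100).
#' @param min_neighbors Minimum neighbor count, self excluded (default 3).
#' @return The filtered subset.
#' @export
density_filter <- function(locs, radius = 100, min_neighbors = 3) {
  stopifnot(radius > 0)
  n <- nrow(locs)
  if (n == 0) return(locs)
  counts <- integer(n)
  r2 <- radius^2
  # cell-list neighbor counting
  cx <- floor(locs$x / radius); cy <- floor(locs$y / radius)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  for (i in seq_len(n)) {
    cand <- unlist(cells[paste(rep(cx[i] + (-1:1), 3),
                               rep(cy[i] + (-1:1), each = 3))],
                   use.names = FALSE)
    d2 <- (locs$x[cand] - locs$x[i])^2 + (locs$y[cand] - locs$y[i])^2
    counts[i] <- sum(d2 <= r2) - 1L
  }
  locs[counts >= min_neighbors, , drop = FALSE]
}

#' Fraction of core-channel spots colocalized with coating clusters
#'
#' The automated counterpart of scoring which labeled nanocapsule cores also
#' show a Nile Red coating signal: the fraction of core spot centroids whose
#' nearest cluster centroid lies within `radius`.
#'
#' @param core_spots data.frame with `x`, `y` (nm) of diffraction-limited
#'   core detections.
#' @param clusters data.frame with cluster centroids `x`, `y` (nm), e.g.
#'   from [cluster_particles()]; may be empty.
#' @param radius Match radius, nm (default 250).
#' @return Fraction in [0, 1].
#' @export
colocalization_fraction <- function(core_spots, clusters, radius = 250) {
  if (is.null(core_spots) || nrow(core_spots) == 0)
    stop("no core spots supplied")
  if (is.null(clusters) || nrow(clusters) == 0) return(0)
  hit <- vapply(seq_len(nrow(core_spots)), function(i) {
    d2 <- (clusters$x - core_spots$x[i])^2 + (clusters$y - core_spots$y[i])^2
    min(d2) <= radius^2
  }, NA)
  mean(hit)
}

#' Write a THUNDERSTORM-compatible localization CSV
#'
#' Header: `frame,"x [nm]","y [nm]","sigma [nm]","intensity [photon]",
#' "offset [photon]","uncertainty_xy [nm]"`.
#'
#' @param locs A `localizations` data.frame.
#' @param path Output CSV path.
#' @export
write_locs <- function(locs, path) {
  df <- data.frame(frame = locs$frame, locs$x, locs$y, locs$sigma,
                   locs$intensity, locs$offset, locs$uncertainty_xy)
  names(df) <- c("frame", "x [nm]", "y [nm]", "sigma [nm]",
                 "intensity [photon]", "offset [photon]",
                 "uncertainty_xy [nm]")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a THUNDERSTORM-style localization CSV
#'
#' @param path CSV with bracketed-unit headers as written by [write_locs()]
#'   (or THUNDERSTORM itself).
#' @return A `localizations` data.frame.
#' @export
read_locs <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pick <- function(stem) {
    hit <- grep(paste0("^", stem), names(df))
    if (length(hit) == 0) stop("missing column '", stem, "' in ", path)
    df[[hit[1]]]
  }
  out <- data.frame(frame = pick("frame"), x = pick("x"), y = pick("y"),
                    sigma = pick("sigma"), intensity = pick("intensity"),
                    offset = pick("offset"),
                    uncertainty_xy = pick("uncertainty"))
  class(out) <- c("localizations", "data.frame")
  out
}
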