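# Membrane structure and dynamics estimators for head-group trajectories:
# area per lipid, head-to-head bilayer thickness, area compressibility
# modulus, and lateral diffusivity via the Einstein relation.

#' Area-per-lipid time series
#'
#' `APL(t) = Lx(t) Ly(t) / n_per_leaflet`, sampled every `interval_ns`
#' (default 10 ns), with mean, sd and standard error over the samples.
#'
#' @param traj A `head_trajectory`.
#' @param interval_ns Sampling interval, ns; samples fall on the stored
#'   times nearest the interval grid.
#' @return An `apl_series` list: `times`, `apl` (nm^2), `mean`, `sd`,
#'   `stderr`, `n`, `temperature`.
#' @export
apl_series <- function(traj, interval_ns = 10) {
  stopifnot(inherits(traj, "head_trajectory"))
  if (is.null(traj$Lx) || is.null(traj$Ly) || anyNA(traj$Lx) || anyNA(traj$Ly))
    stop("trajectory has no box dimensions")
  stopifnot(interval_ns > 0)
  grid <- seq(min(traj$times), max(traj$times), by = interval_ns)
  idx <- unique(vapply(grid, function(t) which.min(abs(traj$times - t)), 0L))
  apl <- traj$Lx[idx] * traj$Ly[idx] / traj$n_per_leaflet
  structure(list(times = traj$times[idx], apl = apl,
                 mean = mean(apl),
                 sd = if (length(apl) > 1) stats::sd(apl) else 0,
                 stderr = if (length(apl) > 1)
                   stats::sd(apl) / sqrt(length(apl)) else NA_real_,
                 n = length(apl), temperature = traj$temperature),
            class = "apl_series")
}

#' Head-to-head bilayer thickness
#'
#' Distance between the two peaks of the head-group z-density: a histogram
#' of all z samples is split at its midpoint, the tallest bin on each side
#' is refined by a parabola through its neighbors, and D_HH is the distance
#' between the refined peaks. Translation invariant in z.
#'
#' @param traj A `head_trajectory`.
#' @param bin_nm Histogram bin width, nm (default 0.05).
#' @return D_HH in nm.
#' @export
bilayer_thickness <- function(traj, bin_nm = 0.05) {
  stopifnot(inherits(traj, "head_trajectory"))
  z <- as.vector(traj$z)
  zc <- mean(z)
  rng <- range(z)
  breaks <- seq(rng[1] - bin_nm, rng[2] + bin_nm, by = bin_nm)
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  peak_side <- function(sel) {
    if (!any(sel)) return(NA_real_)
    cnt <- h$counts; cnt[!sel] <- -1
    i <- which.max(cnt)
    # parabolic refinement through the neighboring bins
    if (i > 1 && i < length(cnt)) {
      y1 <- h$counts[i - 1]; y2 <- h$counts[i]; y3 <- h$counts[i + 1]
      den <- y1 - 2 * y2 + y3
      off <- if (den == 0) 0 else 0.5 * (y1 - y3) / den
    } else off <- 0
    h$mids[i] + off * bin_nm
  }
  upper <- peak_side(h$mids > zc)
  lower <- peak_side(h$mids <= zc)
  if (is.na(upper) || is.na(lower) || (upper - lower) < 2 * bin_nm)
    stop("leaflets unresolved: head-group z-density is unimodal")
  upper - lower
}

#' Area compressibility modulus from APL fluctuations
#'
#' The default `"literal"` mode evaluates the published relation
#' `K_A = k_B T APL / sigma_APL` exactly as printed (Boltzmann constant
#' times temperature times mean area per lipid over its standard deviation),
#' which carries units of energy (J). The `"variance"` mode is the
#' conventional fluctuation estimator `k_B T <A> / Var(A)` on the total box
#' area, reported in mN/m.
#'
#' @param apl An `apl_series` (or the trajectory's APL numeric vector).
#' @param temperature Kelvin; defaults to the series' stored temperature.
#' @param mode `"literal"` (default) or `"variance"`.
#' @param n_per_leaflet Needed for `"variance"` mode when `apl` is a bare
#'   vector.
#' @return K_A (J in literal mode; mN/m in variance mode).
#' @export
compressibility <- function(apl, temperature = NULL,
                            mode = c("literal", "variance"),
                            n_per_leaflet = NULL) {
  mode <- match.arg(mode)
  if (inherits(apl, "apl_series")) {
    if (is.null(temperature)) temperature <- apl$temperature
    vals <- apl$apl
  } else vals <- as.numeric(apl)
  if (is.null(temperature)) stop("temperature is required")
  if (length(vals) < 2) stop("need at least 2 APL samples")
  s <- stats::sd(vals)
  if (s == 0) stop("APL series has zero variance; K_A diverges")
  if (mode == "literal") return(BOLTZMANN * temperature * mean(vals) / s)
  if (is.null(n_per_leaflet))
    stop("variance mode needs n_per_leaflet to recover the total box area")
  area <- vals * n_per_leaflet              # nm^2 total box area
  ka_j_per_nm2 <- BOLTZMANN * temperature * mean(area) / stats::var(area)
  ka_j_per_nm2 * 1e18 * 1e3                 # J/nm^2 -> J/m^2 -> mN/m
}

#' Ensemble mean-square displacement of head groups
#'
#' Lateral (x, y) MSD using all time origins, after periodic-boundary
#' unwrapping with the per-step minimum-image convention.
#'
#' @param traj A `head_trajectory` (coordinates may be box-wrapped).
#' @param lags Integer step lags at which to evaluate; default an
#'   approximately uniform grid of at most `max_lags` lags.
#' @param max_lags Cap on the number of evaluated lags.
#' @return Data.frame `lag`, `tau_ns`, `msd` (nm^2).
#' @export
msd_lateral <- function(traj, lags = NULL, max_lags = 200) {
  stopifnot(inherits(traj, "head_trajectory"))
  n <- nrow(traj$x)
  if (is.null(lags)) {
    lags <- unique(round(seq(1, n - 1, length.out = min(max_lags, n - 1))))
  }
  stopifnot(all(lags >= 1), all(lags <= n - 1))
  ux <- unwrap_coords(traj$x, traj$Lx)
  uy <- unwrap_coords(traj$y, traj$Ly)
  dt <- traj$times[2] - traj$times[1]
  msd <- vapply(lags, function(k) {
    dx <- ux[(k + 1):n, , drop = FALSE] - ux[1:(n - k), , drop = FALSE]
    dy <- uy[(k + 1):n, , drop = FALSE] - uy[1:(n - k), , drop = FALSE]
    mean(dx^2 + dy^2)
  }, 0)
  data.frame(lag = lags, tau_ns = lags * dt, msd = msd)
}

#' Unwrap periodic coordinates
#'
#' Reconstructs continuous trajectories from box-wrapped ones by the
#' minimum-image convention applied to successive displacements, using the
#' per-step box length.
#'
#' @param w Matrix `[time, head]` of wrapped coordinates, nm.
#' @param L Box length per time step (vector or scalar), nm.
#' @return Matrix of unwrapped coordinates.
#' @export
unwrap_coords <- function(w, L) {
  n <- nrow(w)
  if (n < 2) return(w)
  L <- rep_len(L, n)
  d <- w[-1, , drop = FALSE] - w[-n, , drop = FALSE]
  d <- d - round(d / L[-1]) * L[-1]
  out <- w
  out[-1, ] <- d
  apply(out, 2, cumsum)
}

#' Lateral diffusion coefficient by the Einstein relation
#'
#' Fits `MSD = intercept + slope * tau` over a window of the trajectory span
#' (default 8% to 72.5%, mirroring a 1.6-14.5 us fit range on a 20 us run)
#' and returns `D = slope / (2 d)` with `d = 2` lateral dimensions, with
#' the fit standard error. A low linear-fit R^2 flags non-diffusive
#' (e.g. ballistic) motion.
#'
#' @param traj A `head_trajectory`.
#' @param fit_window_fraction Two fractions of the total span delimiting the
#'   fitted tau range.
#' @param r2_threshold Minimum R^2 for a clean diffusive fit (default 0.9).
#' @param alpha_band Acceptable band for the log-log diffusive exponent
#'   (1 for Brownian motion, 2 for ballistic); outside it the fit is
#'   flagged.
#' @param max_lags Lag grid size passed to [msd_lateral()].
#' @return A `diffusivity_fit` list: `D` (um^2/s), `D_se`, `slope_nm2_ns`,
#'   `r_squared`, `alpha` (log-log exponent), `poor_fit`, `fit_range_ns`,
#'   `msd`.
#' @export
lateral_diffusivity <- function(traj, fit_window_fraction = c(0.08, 0.725),
                                r2_threshold = 0.9,
                                alpha_band = c(0.7, 1.3), max_lags = 200) {
  stopifnot(inherits(traj, "head_trajectory"), ncol(traj$x) >= 2)
  span <- max(traj$times) - min(traj$times)
  win <- fit_window_fraction * span
  if (win[1] >= win[2] || win[2] > span)
    stop("fit window outside trajectory span")
  msd <- msd_lateral(traj, max_lags = max_lags)
  sel <- msd$tau_ns >= win[1] & msd$tau_ns <= win[2]
  if (sum(sel) < 2) stop("fit window contains fewer than 2 MSD points")
  fit <- stats::lm(msd ~ tau_ns, data = msd[sel, ])
  sm <- summary(fit)
  slope <- stats::coef(fit)[["tau_ns"]]              # nm^2 / ns
  se <- sm$coefficients["tau_ns", "Std. Error"]
  # log-log diffusive exponent: ~1 for Brownian, ~2 for ballistic motion
  pos <- sel & msd$msd > 0
  alpha <- if (sum(pos) >= 2)
    stats::coef(stats::lm(log(msd) ~ log(tau_ns),
                          data = msd[pos, ]))[[2]] else NA_real_
  immobile <- all(msd$msd[sel] < 1e-12)
  d_dim <- 2
  structure(list(D = slope * 1e3 / (2 * d_dim),      # nm^2/ns -> um^2/s
                 D_se = se * 1e3 / (2 * d_dim),
                 slope_nm2_ns = slope,
                 r_squared = sm$r.squared,
                 alpha = alpha,
                 poor_fit = !immobile &&
                   (sm$r.squared < r2_threshold || is.na(alpha) ||
                      alpha < alpha_band[1] || alpha > alpha_band[2]),
                 fit_range_ns = win, msd = msd),
            class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf("Lateral diffusivity: D = %.4g +/- %.2g um^2/s (R^2 = %.4f%s)\n",
              x$D, x$D_se, x$r_squared,
              if (x$poor_fit) ", POOR LINEAR FIT" else ""))
  cat(sprintf("  fitted over tau = %.3g - %.3g ns\n",
              x$fit_range_ns[1], x$fit_range_ns[2]))
  invisible(x)
}

#' All membrane metrics for one trajectory
#'
#' @param traj A `head_trajectory`.
#' @param temperature Kelvin; defaults to the trajectory's.
#' @param interval_ns APL sampling interval.
#' @param ... Passed to [lateral_diffusivity()].
#' @return A `membrane_metrics` list: `apl` (series), `d_hh` (nm), `k_a_J`
#'   (literal mode), `k_a_mN_m` (variance mode), `diffusivity`.
#' @export
membrane_metrics <- function(traj, temperature = NULL, interval_ns = 10,
                             ...) {
  if (is.null(temperature)) temperature <- traj$temperature
  ap <- apl_series(traj, interval_ns)
  structure(list(
    apl = ap,
    d_hh = bilayer_thickness(traj),
    k_a_J = compressibility(ap, temperature, mode = "literal"),
    k_a_mN_m = compressibility(ap, temperature, mode = "variance",
                               n_per_leaflet = traj$n_per_leaflet),
    diffusivity = lateral_diffusivity(traj, ...),
    temperature = temperature),
    class = "membrane_metrics")
}

#' @export
print.membrane_metrics <- function(x, ...) {
  cat("Membrane metrics\n")
  cat(sprintf("  APL: %.4f +/- %.4f nm^2 (stderr, n = %d)\n",
              x$apl$mean, x$apl$stderr, x$apl$n))
  cat(sprintf("  D_HH: %.3f nm\n", x$d_hh))
  cat(sprintf("  K_A: %.4g J (as-printed relation) | %.4g mN/m (variance)\n",
              x$k_a_J, x$k_a_mN_m))
  print(x$diffusivity)
  invisible(x)
}

#' JSON export of membrane metrics
#' @param m A `membrane_metrics` object.
#' @param path Output JSON path.
#' @export
write_membrane_metrics <- function(m, path) {
  jsonlite::write_json(list(
    apl_mean_nm2 = m$apl$mean, apl_stderr_nm2 = m$apl$stderr,
    apl_n = m$apl$n, d_hh_nm = m$d_hh, k_a_literal_J = m$k_a_J,
    k_a_variance_mN_m = m$k_a_mN_m, D_um2_s = m$diffusivity$D,
    D_se_um2_s = m$diffusivity$D_se,
    r_squared = m$diffusivity$r_squared,
    temperature_K = m$temperature),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
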