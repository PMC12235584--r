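# Flat-kernel mean-shift clustering of QC-passed localizations into
# particles, frame-run linking into bright/dark times, and per-cluster
# summary statistics.

#' Flat-kernel mean-shift clustering of localizations
#'
#' Every point is iterated to its density mode: the current position is
#' replaced by the mean of all input points within `bandwidth` until the
#' shift falls below `tol`. Modes closer than `bandwidth / 2` are merged
#' (single linkage) and every localization is assigned to exactly one merged
#' mode.
#'
#' @param xy Two-column matrix or data.frame of positions (nm); typically
#'   the `x`, `y` of QC-passed spectral fits.
#' @param bandwidth Flat kernel radius, nm (default 100).
#' @param tol Convergence tolerance on the shift, nm.
#' @param max_iter Maximum mean-shift iterations.
#' @return List with `assignment` (integer cluster id per input row, order
#'   independent of input order up to relabeling), `modes` (matrix of merged
#'   mode centers), `n_clusters`.
#' @export
mean_shift_cluster <- function(xy, bandwidth = 100, tol = 0.1,
                               max_iter = 200) {
  stopifnot(bandwidth > 0)
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (n == 0)
    return(list(assignment = integer(0),
                modes = matrix(numeric(0), 0, 2), n_clusters = 0L))
  bw2 <- bandwidth^2
  cur <- xy
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    for (i in idx) {
      d2 <- (xy[, 1] - cur[i, 1])^2 + (xy[, 2] - cur[i, 2])^2
      nb <- d2 <= bw2
      new <- c(mean(xy[nb, 1]), mean(xy[nb, 2]))
      if (sum((new - cur[i, ])^2) < tol^2) active[i] <- FALSE
      cur[i, ] <- new
    }
  }
  # merge modes closer than bandwidth/2 by single linkage
  uniq <- unique(round(cur, 3))
  if (nrow(uniq) == 1) {
    merged_id <- rep(1L, nrow(uniq))
  } else {
    hc <- stats::hclust(stats::dist(uniq), method = "single")
    merged_id <- stats::cutree(hc, h = bandwidth / 2)
  }
  # map each point's mode to its merged cluster
  key <- function(m) paste(m[, 1], m[, 2])
  mode_of_point <- match(key(round(cur, 3)), key(uniq))
  assignment <- merged_id[mode_of_point]
  k <- max(assignment)
  modes <- t(vapply(seq_len(k), function(c)
    colMeans(xy[assignment == c, , drop = FALSE]), numeric(2)))
  # relabel deterministically by mode position for order invariance
  ord <- order(modes[, 1], modes[, 2])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(assignment = relabel[assignment],
       modes = modes[ord, , drop = FALSE], n_clusters = k)
}

#' Link a cluster's frames into bright and dark times
#'
#' Consecutive-frame runs (allowing gaps up to `max_gap_frames`) form single
#' binding events; a run spanning frames f1..f2 has bright time
#' `(f2 - f1 + 1) * exposure` and the gap to the next run contributes a dark
#' time of `gap * exposure`.
#'
#' @param frames Integer frames in which the cluster was localized.
#' @param max_gap_frames Frames of tolerated dark gap inside one event
#'   (default 0 = strictly consecutive).
#' @param exposure Frame exposure, ms (default 50).
#' @return List `bright_ms`, `dark_ms`, `n_events`.
#' @export
link_events <- function(frames, max_gap_frames = 0, exposure = 50) {
  frames <- sort(unique(as.integer(frames)))
  if (length(frames) == 0)
    return(list(bright_ms = numeric(0), dark_ms = numeric(0), n_events = 0L))
  brk <- which(diff(frames) > max_gap_frames + 1)
  starts <- frames[c(1, brk + 1)]
  ends <- frames[c(brk, length(frames))]
  bright <- (ends - starts + 1) * exposure
  dark <- if (length(starts) > 1)
    (starts[-1] - ends[-length(ends)] - 1) * exposure else numeric(0)
  list(bright_ms = bright, dark_ms = dark, n_events = length(starts))
}

.mean_sd <- function(v) {
  if (length(v) == 0) return(c(NA_real_, NA_real_))
  c(mean(v), if (length(v) > 1) stats::sd(v) else 0)
}

#' Summarize one particle cluster
#'
#' Computes the per-cluster outputs: mean and sd of bright times, dark
#' times, centroid wavelengths, peak wavelengths, spatial and spectral
#' photons; the number of binding events; a cluster diameter defined as
#' `2 sqrt(2)` times the RMS distance of members from the centroid (unbiased
#' for a uniform disc); and the aspect ratio `sqrt(l1/l2)` of the position
#' covariance eigenvalues. Single-member clusters report sd 0 and are
#' flagged.
#'
#' @param members Data.frame of member fits (needs `frame`, `x`, `y`;
#'   optionally `peak_wavelength`, `centroid_wavelength`, `photons_spatial`,
#'   `photons_spectral`).
#' @param id Cluster id.
#' @param exposure Frame exposure, ms.
#' @param max_gap_frames Gap tolerance for [link_events()].
#' @param min_events Events needed for `validated = TRUE` (default 5).
#' @return One-row data.frame of cluster summaries.
#' @export
summarize_cluster <- function(members, id = 1L, exposure = 50,
                              max_gap_frames = 0, min_events = 5) {
  stopifnot(nrow(members) >= 1)
  cx <- mean(members$x); cy <- mean(members$y)
  d2 <- (members$x - cx)^2 + (members$y - cy)^2
  diameter <- 2 * sqrt(2) * sqrt(mean(d2))
  if (nrow(members) > 1 && diameter > 0) {
    ev <- eigen(stats::cov(cbind(members$x, members$y)),
                symmetric = TRUE, only.values = TRUE)$values
    aspect <- sqrt(max(ev[1], 0) / max(ev[2], 1e-12))
  } else aspect <- 1
  lk <- link_events(members$frame, max_gap_frames, exposure)
  g <- function(col) if (col %in% names(members))
    .mean_sd(members[[col]][!is.na(members[[col]])]) else c(NA_real_, NA_real_)
  bt <- .mean_sd(lk$bright_ms); dk <- .mean_sd(lk$dark_ms)
  pw <- g("peak_wavelength"); cw <- g("centroid_wavelength")
  ps <- g("photons_spatial"); pp <- g("photons_spectral")
  data.frame(
    cluster = id, n_locs = nrow(members), x = cx, y = cy,
    diameter = diameter, aspect_ratio = aspect,
    n_events = lk$n_events,
    bright_mean_ms = bt[1], bright_sd_ms = bt[2],
    dark_mean_ms = dk[1], dark_sd_ms = dk[2],
    peak_wavelength_mean = pw[1], peak_wavelength_sd = pw[2],
    centroid_wavelength_mean = cw[1], centroid_wavelength_sd = cw[2],
    photons_spatial_mean = ps[1], photons_spatial_sd = ps[2],
    photons_spectral_mean = pp[1], photons_spectral_sd = pp[2],
    single_member = nrow(members) == 1,
    validated = lk$n_events >= min_events)
}

#' Cluster QC-passed fits into particles and summarize them
#'
#' Runs [mean_shift_cluster()] on positions, then [summarize_cluster()] per
#' cluster.
#'
#' @param fits Data.frame of QC-passed spectral fits (or any localization
#'   table with `frame`, `x`, `y`).
#' @param bandwidth Mean-shift bandwidth, nm (default 100).
#' @param exposure Frame exposure, ms.
#' @param max_gap_frames Gap tolerance for event linking.
#' @param min_events Validation threshold on event count.
#' @return A `particle_clusters` object: list with `clusters` (one summary
#'   row per cluster), `assignment` (cluster id per input fit), `fits`.
#' @export
cluster_particles <- function(fits, bandwidth = 100, exposure = 50,
                              max_gap_frames = 0, min_events = 5) {
  if (nrow(fits) == 0) {
    return(structure(list(clusters = data.frame(), assignment = integer(0),
                          fits = fits), class = "particle_clusters"))
  }
  ms <- mean_shift_cluster(cbind(fits$x, fits$y), bandwidth)
  summaries <- do.call(rbind, lapply(seq_len(ms$n_clusters), function(c)
    summarize_cluster(fits[ms$assignment == c, , drop = FALSE], id = c,
                      exposure = exposure, max_gap_frames = max_gap_frames,
                      min_events = min_events)))
  structure(list(clusters = summaries, assignment = ms$assignment,
                 fits = fits),
            class = "particle_clusters")
}

#' @export
print.particle_clusters <- function(x, ...) {
  cl <- x$clusters
  cat(sprintf("%d particle clusters from %d localizations (%d validated)\n",
              nrow(cl), nrow(x$fits), sum(cl$validated)))
  if (nrow(cl)) {
    cat(sprintf("  diameter %.0f +/- %.0f nm; peak wavelength %.1f +/- %.1f nm\n",
                mean(cl$diameter), stats::sd(cl$diameter),
                mean(cl$peak_wavelength_mean, na.rm = TRUE),
                stats::sd(cl$peak_wavelength_mean, na.rm = TRUE)))
  }
  invisible(x)
}

#' Validated clusters of a `particle_clusters` object
#' @param pc A `particle_clusters` object.
#' @return The validated subset of the cluster summary table.
#' @export
validated_clusters <- function(pc) {
  stopifnot(inherits(pc, "particle_clusters"))
  pc$clusters[pc$clusters$validated, , drop = FALSE]
}
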