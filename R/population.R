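# Population-level wavelength distribution comparison: pooled histograms,
# zero-lag cross-correlation similarity against a reference, and
# inter-/intra-particle heterogeneity.

#' Pooled wavelength histogram of validated clusters
#'
#' At `"localization"` level all member wavelengths of validated clusters
#' are pooled; at `"cluster_mean"` level each validated cluster contributes
#' its single mean wavelength. Densities are normalized so that
#' `sum(density * binwidth) = 1`.
#'
#' @param pc A `particle_clusters` object (or a plain numeric vector of
#'   wavelengths).
#' @param level `"localization"` or `"cluster_mean"`.
#' @param statistic `"peak"` (default) or `"centroid"` wavelength.
#' @param binwidth Bin width, nm (default 2).
#' @param range Histogram support, nm (default 550-700).
#' @param label Sample label.
#' @return A `wavelength_histogram` list: `breaks`, `mids`, `density`,
#'   `counts`, `n`, `binwidth`, `label`.
#' @export
pooled_histogram <- function(pc, level = c("localization", "cluster_mean"),
                             statistic = c("peak", "centroid"), binwidth = 2,
                             range = c(550, 700), label = "sample") {
  level <- match.arg(level)
  statistic <- match.arg(statistic)
  col <- if (statistic == "peak") "peak_wavelength" else "centroid_wavelength"
  if (is.numeric(pc)) {
    wl <- pc
  } else {
    stopifnot(inherits(pc, "particle_clusters"))
    val <- validated_clusters(pc)
    if (nrow(val) == 0) stop("no validated clusters to pool")
    if (level == "cluster_mean") {
      wl <- val[[paste0(col, "_mean")]]
    } else {
      keep <- pc$assignment %in% val$cluster
      wl <- pc$fits[[col]][keep]
    }
  }
  wl <- wl[!is.na(wl)]
  if (length(wl) == 0) stop("no wavelengths to pool")
  breaks <- seq(range[1], range[2], by = binwidth)
  wl <- pmin(pmax(wl, range[1]), range[2])
  counts <- graphics::hist(wl, breaks = breaks, plot = FALSE)$counts
  density <- counts / (sum(counts) * binwidth)
  structure(list(breaks = breaks, mids = breaks[-length(breaks)] + binwidth / 2,
                 density = density, counts = counts, n = length(wl),
                 binwidth = binwidth, label = label),
            class = "wavelength_histogram")
}

#' @export
print.wavelength_histogram <- function(x, ...) {
  m <- sum(x$mids * x$density) * x$binwidth
  cat(sprintf(
    "Wavelength histogram '%s': n = %d, %g nm bins on [%g, %g], mean %.1f nm\n",
    x$label, x$n, x$binwidth, min(x$breaks), max(x$breaks), m))
  invisible(x)
}

#' @export
plot.wavelength_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "h", xlab = "wavelength (nm)",
                 ylab = "density (1/nm)", main = x$label, ...)
  invisible(x)
}

#' Zero-lag cross-correlation similarity of two wavelength histograms
#'
#' Pearson correlation between the matched-bin density vectors; 1 for
#' identical shapes, non-positive for disjoint supports. Invariant to any
#' common rescaling of the densities.
#'
#' @param h,ref `wavelength_histogram` objects on identical bins.
#' @return Correlation coefficient in [-1, 1].
#' @export
cross_correlation <- function(h, ref) {
  stopifnot(inherits(h, "wavelength_histogram"),
            inherits(ref, "wavelength_histogram"))
  if (length(h$breaks) != length(ref$breaks) ||
      any(abs(h$breaks - ref$breaks) > 1e-9))
    stop("histograms must share identical binning")
  if (identical(h$density, ref$density)) return(1)
  min(1, max(-1, stats::cor(h$density, ref$density)))
}

#' Similarity report against a reference population
#'
#' @param samples Named list of `wavelength_histogram` objects.
#' @param ref Reference `wavelength_histogram`.
#' @param threshold Similarity threshold (default 0.9; coefficients above it
#'   are flagged as significantly similar).
#' @return A `similarity_report` data.frame: `sample`, `coefficient`,
#'   `similar`.
#' @export
similarity_report <- function(samples, ref, threshold = 0.9) {
  cc <- vapply(samples, cross_correlation, 0, ref = ref)
  out <- data.frame(sample = names(samples), coefficient = cc,
                    similar = cc > threshold, row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "reference") <- ref$label
  class(out) <- c("similarity_report", "data.frame")
  out
}

#' Inter- and intra-particle wavelength heterogeneity
#'
#' Inter-particle: distribution (and sd) of validated-cluster mean
#' wavelengths. Intra-particle: distribution of within-cluster sds (clusters
#' with at least two events) and its median.
#'
#' @param pc A `particle_clusters` object.
#' @param statistic `"peak"` or `"centroid"`.
#' @return A `heterogeneity_report` list: `cluster_means`, `inter_sd`,
#'   `cluster_sds`, `intra_median`, `n_clusters`.
#' @export
heterogeneity_report <- function(pc, statistic = c("peak", "centroid")) {
  statistic <- match.arg(statistic)
  val <- validated_clusters(pc)
  col_m <- paste0(if (statistic == "peak") "peak_wavelength"
                  else "centroid_wavelength", "_mean")
  col_s <- sub("_mean$", "_sd", col_m)
  means <- val[[col_m]]
  sds <- val[[col_s]][val$n_locs >= 2]
  structure(list(
    cluster_means = means,
    inter_sd = if (length(means) >= 2) stats::sd(means) else NA_real_,
    cluster_sds = sds,
    intra_median = if (length(sds)) stats::median(sds) else NA_real_,
    n_clusters = nrow(val)),
    class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Heterogeneity over %d validated clusters\n", x$n_clusters))
  cat(sprintf("  inter-particle sd of cluster means: %s nm\n",
              if (is.na(x$inter_sd)) "n/a (needs >= 2 clusters)"
              else sprintf("%.2f", x$inter_sd)))
  cat(sprintf("  median intra-particle sd: %s nm\n",
              if (is.na(x$intra_median)) "n/a"
              else sprintf("%.2f", x$intra_median)))
  invisible(x)
}
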