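# Coating stoichiometry budget: hollow-shell nanocapsule mass vs the lipid
# mass needed for a single two-leaflet bilayer coat, across a size
# distribution.

#' Nanocapsule geometry
#'
#' @param outer_diameter Outer diameter in nm.
#' @param wall_thickness Shell wall thickness in nm.
#' @param density Silica density in g/cm^3 (default 1.87, the sol-gel
#'   literature value).
#' @return An `nc_geometry` list.
#' @export
nc_geometry <- function(outer_diameter = 79.4, wall_thickness = 3.68,
                        density = 1.87) {
  stopifnot(outer_diameter > 0, wall_thickness > 0, density > 0)
  if (2 * wall_thickness > outer_diameter)
    stop("wall thickness exceeds radius: 2*t must be <= outer diameter")
  structure(list(outer_diameter = outer_diameter,
                 wall_thickness = wall_thickness,
                 density = density),
            class = "nc_geometry")
}

#' Mass of a hollow organosilica nanocapsule
#'
#' Treats the capsule as a perfect hollow sphere: the shell volume
#' (4/3)pi(r_o^3 - (r_o - t)^3) in nm^3 times the silica density, with
#' nm^3 -> cm^3 conversion (1 nm^3 = 1e-21 cm^3).
#'
#' @param g An [nc_geometry()] object.
#' @return Shell mass in grams.
#' @export
nc_shell_mass <- function(g) {
  stopifnot(inherits(g, "nc_geometry"))
  r_o <- g$outer_diameter / 2
  r_i <- r_o - g$wall_thickness
  vol_nm3 <- (4 / 3) * pi * (r_o^3 - r_i^3)
  vol_nm3 * 1e-21 * g$density
}

#' Number of lipid molecules in a single bilayer coat
#'
#' Closed-form two-leaflet area model: the inner leaflet sits on the capsule
#' surface (radius d/2), the outer leaflet at d/2 + bilayer thickness; the
#' summed sphere areas are divided by an effective per-molecule area.
#' In the default `"uniform"` mode one effective area is used for every
#' species; `"per_species"` uses the mole-fraction-weighted mean of the
#' catalog reference areas.
#'
#' @param d_nc Nanocapsule outer diameter in nm.
#' @param f A [formulation()] (required only for `"per_species"` mode).
#' @param t_bilayer Bilayer geometric thickness in nm (default 4.0).
#' @param a_eff Uniform effective area per molecule, nm^2 (default 0.72).
#' @param area_mode `"uniform"` or `"per_species"`.
#' @return Total molecules (inner + outer leaflet), a positive number.
#' @export
bilayer_molecule_count <- function(d_nc, f = NULL, t_bilayer = 4.0,
                                   a_eff = 0.72,
                                   area_mode = c("uniform", "per_species")) {
  area_mode <- match.arg(area_mode)
  stopifnot(d_nc > 0, t_bilayer > 0, a_eff > 0)
  r_in <- d_nc / 2
  r_out <- d_nc / 2 + t_bilayer
  if (area_mode == "per_species") {
    if (is.null(f)) stop("per_species area mode needs a formulation")
    validate_formulation(f)
    a_eff <- sum(f$mole_fraction * f$ref_area)
  }
  (4 * pi * r_in^2 + 4 * pi * r_out^2) / a_eff
}

#' Mass of a single bilayer coat
#'
#' Molecule count times the formulation's mole-fraction-weighted molar mass,
#' divided by Avogadro's number.
#'
#' @inheritParams bilayer_molecule_count
#' @return Bilayer mass in grams.
#' @export
bilayer_mass <- function(d_nc, f, t_bilayer = 4.0, a_eff = 0.72,
                         area_mode = c("uniform", "per_species")) {
  area_mode <- match.arg(area_mode)
  n <- bilayer_molecule_count(d_nc, f, t_bilayer, a_eff, area_mode)
  n * mean_molar_mass(f) / AVOGADRO
}

#' Nanocapsule:lipid mass ratio across a diameter grid
#'
#' For each diameter the hollow-shell capsule mass (wall thickness and
#' density held fixed at the template's values) is divided by the mass of a
#' single bilayer coat of that diameter.
#'
#' @param f A [formulation()].
#' @param geom_template [nc_geometry()] supplying wall thickness and density.
#' @param diameters Diameter grid in nm (default 45-125 step 5).
#' @param t_bilayer,a_eff,area_mode Passed to [bilayer_mass()].
#' @return A `ratio_curve` data.frame with columns `diameter_nm`,
#'   `nc_mass_g`, `lipid_mass_g`, `ratio`.
#' @export
ratio_curve <- function(f, geom_template = nc_geometry(),
                        diameters = seq(45, 125, by = 5),
                        t_bilayer = 4.0, a_eff = 0.72,
                        area_mode = c("uniform", "per_species")) {
  area_mode <- match.arg(area_mode)
  validate_formulation(f)
  stopifnot(all(diameters > 0), !is.unsorted(diameters, strictly = TRUE))
  nc_mass <- vapply(diameters, function(d)
    nc_shell_mass(nc_geometry(d, geom_template$wall_thickness,
                              geom_template$density)), 0)
  lip_mass <- vapply(diameters, function(d)
    bilayer_mass(d, f, t_bilayer, a_eff, area_mode), 0)
  out <- data.frame(diameter_nm = diameters, nc_mass_g = nc_mass,
                    lipid_mass_g = lip_mass, ratio = nc_mass / lip_mass)
  attr(out, "formulation_label") <- attr(f, "label")
  class(out) <- c("ratio_curve", "data.frame")
  out
}

#' Truncated-normal nanocapsule size distribution
#'
#' Analytic bin masses of a normal distribution truncated to the support,
#' on a uniform 5 nm grid; frequencies sum to exactly 100.
#'
#' @param mean,sd Mean and sd of the underlying normal, nm (defaults are the
#'   TEM estimates 79.4 and 11.6).
#' @param support Truncation interval, nm.
#' @param bin_width Bin width, nm (default 5).
#' @return A `size_distribution` data.frame with `bin_lo`, `bin_hi`,
#'   `diameter_mid`, `frequency` (percent).
#' @export
size_distribution_truncnorm <- function(mean = 79.4, sd = 11.6,
                                        support = c(45, 125), bin_width = 5) {
  stopifnot(sd > 0, support[2] > support[1],
            (support[2] - support[1]) %% bin_width == 0)
  edges <- seq(support[1], support[2], by = bin_width)
  p <- diff(stats::pnorm(edges, mean, sd))
  freq <- 100 * p / sum(p)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    diameter_mid = edges[-length(edges)] + bin_width / 2,
                    frequency = freq)
  class(out) <- c("size_distribution", "data.frame")
  out
}

#' Frequency-weighted nanocapsule:lipid mass ratio
#'
#' Weights each diameter's ratio by the percent frequency of that diameter
#' bin in the size distribution: sum(ratio(d) * freq(d) / 100). Curve
#' diameters must cover every distribution bin (bins are matched to the
#' curve diameter nearest the bin midpoint, within half a bin).
#'
#' @param curve A [ratio_curve()].
#' @param dist A [size_distribution_truncnorm()]-style data.frame.
#' @return The weighted dimensionless ratio.
#' @export
weighted_ratio <- function(curve, dist) {
  stopifnot(inherits(curve, "ratio_curve"),
            all(c("diameter_mid", "frequency") %in% names(dist)))
  idx <- vapply(dist$diameter_mid, function(d)
    which.min(abs(curve$diameter_nm - d)), 0L)
  off <- abs(curve$diameter_nm[idx] - dist$diameter_mid)
  half_bin <- if (nrow(dist) > 1) diff(dist$bin_lo[1:2]) / 2 else
    (dist$bin_hi[1] - dist$bin_lo[1]) / 2
  if (any(off > half_bin))
    stop("size distribution bins fall outside the ratio curve's diameter range")
  sum(curve$ratio[idx] * dist$frequency) / 100
}

#' Full coating-budget report
#'
#' Per-diameter capsule and bilayer masses and their ratio, plus the
#' size-distribution-weighted ratio, for one formulation. Both the uniform
#' and per-species area modes are reported.
#'
#' @param f A [formulation()].
#' @param geom [nc_geometry()] template.
#' @param dist Size distribution for weighting (default truncated normal
#'   79.4 +/- 11.6 nm on 45-125 nm).
#' @param ... Passed to [ratio_curve()].
#' @return A `budget_report` list with elements `curve` (uniform-area mode),
#'   `curve_per_species`, `weighted_ratio`, `weighted_ratio_per_species`.
#' @export
budget_report <- function(f, geom = nc_geometry(),
                          dist = size_distribution_truncnorm(), ...) {
  cu <- ratio_curve(f, geom, area_mode = "uniform", ...)
  cp <- ratio_curve(f, geom, area_mode = "per_species", ...)
  structure(list(formulation_label = attr(f, "label"),
                 curve = cu, curve_per_species = cp,
                 weighted_ratio = weighted_ratio(cu, dist),
                 weighted_ratio_per_species = weighted_ratio(cp, dist)),
            class = "budget_report")
}

#' @export
print.budget_report <- function(x, ...) {
  cat(sprintf("Coating budget for %s\n", x$formulation_label))
  cat(sprintf("  per-diameter NC:lipid ratio (uniform area): %.2f - %.2f\n",
              min(x$curve$ratio), max(x$curve$ratio)))
  cat(sprintf("  weighted ratio: %.3f (uniform) / %.3f (per-species)\n",
              x$weighted_ratio, x$weighted_ratio_per_species))
  invisible(x)
}

#' @export
print.ratio_curve <- function(x, ...) {
  cat(sprintf("NC:lipid mass ratio curve for %s (%d diameters)\n",
              attr(x, "formulation_label"), nrow(x)))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.ratio_curve <- function(x, ...) {
  graphics::plot(x$diameter_nm, x$ratio, type = "b", pch = 16,
                 xlab = "NC diameter (nm)", ylab = "NC:lipid mass ratio",
                 main = attr(x, "formulation_label"), ...)
  invisible(x)
}
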