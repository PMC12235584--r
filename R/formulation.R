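#' @keywords internal
"_PACKAGE"

KNOWN_FAMILIES <- c("Chol", "SM", "PE", "PC", "PS", "PA")
AVOGADRO <- 6.02214076e23
BOLTZMANN <- 1.380649e-23 # J/K

#' Load the packaged lipid catalog
#'
#' Returns the physical constants (supplier-catalog molar mass, reference
#' per-molecule leaflet area, lipid family) for every commercial species used
#' in the mimic formulations.
#'
#' @param path Optional path to a catalog YAML; defaults to the packaged one.
#' @return A data.frame with columns `species`, `name`, `family`,
#'   `molar_mass` (g/mol), `ref_area` (nm^2 per molecule).
#' @export
lipid_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lipid_catalog.yaml", package = "mimicscope")
  }
  raw <- yaml::read_yaml(path)$species
  out <- data.frame(
    species    = names(raw),
    name       = vapply(raw, function(s) s$name, ""),
    family     = vapply(raw, function(s) s$family, ""),
    molar_mass = vapply(raw, function(s) as.numeric(s$molar_mass), 0),
    ref_area   = vapply(raw, function(s) as.numeric(s$ref_area), 0),
    row.names  = NULL, stringsAsFactors = FALSE
  )
  stopifnot(all(out$molar_mass > 0), all(out$ref_area > 0),
            all(out$family %in% KNOWN_FAMILIES))
  out
}

#' Construct a lipid formulation
#'
#' A formulation is an ordered set of lipid species with mass percentages.
#' Mass fractions must total 100% within a small tolerance (published
#' composition tables round to one decimal and can sum to 99.9).
#'
#' @param label Formulation name, e.g. `"CE Mimic 3"`.
#' @param mass_fraction Named numeric vector of mass percentages; names are
#'   species keys of [lipid_catalog()].
#' @param catalog Catalog data.frame; defaults to the packaged one.
#' @return An object of class `formulation`: a data.frame of species with
#'   mass fractions, molar masses, reference areas and derived mole
#'   fractions, with the label as attribute.
#' @export
formulation <- function(label, mass_fraction, catalog = lipid_catalog()) {
  stopifnot(is.numeric(mass_fraction), length(mass_fraction) >= 1,
            !is.null(names(mass_fraction)))
  unknown <- setdiff(names(mass_fraction), catalog$species)
  if (length(unknown) > 0)
    stop("unknown species in formulation: ", paste(unknown, collapse = ", "))
  idx <- match(names(mass_fraction), catalog$species)
  f <- data.frame(
    species       = names(mass_fraction),
    family        = catalog$family[idx],
    mass_fraction = as.numeric(mass_fraction),
    molar_mass    = catalog$molar_mass[idx],
    ref_area      = catalog$ref_area[idx],
    stringsAsFactors = FALSE
  )
  # mole fractions: x_i proportional to w_i / M_i
  m <- f$mass_fraction / f$molar_mass
  f$mole_fraction <- m / sum(m)
  attr(f, "label") <- label
  class(f) <- c("formulation", "data.frame")
  validate_formulation(f)
}

#' Validate a formulation
#'
#' Checks that mass fractions are non-negative and total 100 +/- 0.2 percent,
#' that all species carry positive molar masses and reference areas, and
#' that lipid families are known.
#'
#' @param f A [formulation()] object.
#' @return `f` unchanged, invisibly validated.
#' @export
validate_formulation <- function(f) {
  stopifnot(inherits(f, "formulation"), nrow(f) >= 1)
  if (any(f$mass_fraction < 0)) stop("negative mass fraction")
  if (any(f$molar_mass <= 0)) stop("non-positive molar mass")
  if (any(f$ref_area <= 0)) stop("non-positive reference area")
  bad <- !f$family %in% KNOWN_FAMILIES
  if (any(bad))
    stop("unknown lipid family: ", paste(unique(f$family[bad]), collapse = ", "))
  s <- sum(f$mass_fraction)
  if (abs(s - 100) > 0.2)
    stop(sprintf("mass fractions sum to %.4g, expected 100 +/- 0.2", s))
  f
}

#' Mean molar mass of a formulation
#'
#' Mole-fraction-weighted molar mass, equal to the harmonic mean of species
#' molar masses weighted by mass fraction.
#'
#' @param f A [formulation()] object.
#' @return Mean molar mass in g/mol.
#' @export
mean_molar_mass <- function(f) {
  validate_formulation(f)
  sum(f$mole_fraction * f$molar_mass)
}

#' Load a packaged formulation by key
#'
#' @param key One of `"mimic-1" ... "mimic-3"`, `"ce-mimic-1" ... "ce-mimic-3"`,
#'   or `NULL` to list available keys.
#' @param path Optional alternative formulations YAML.
#' @param catalog Catalog data.frame passed to [formulation()].
#' @return A `formulation` object, or a character vector of keys if
#'   `key = NULL`.
#' @export
load_formulation <- function(key = NULL, path = NULL, catalog = lipid_catalog()) {
  if (is.null(path)) {
    path <- system.file("extdata", "formulations.yaml", package = "mimicscope")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(key)) return(names(raw))
  if (!key %in% names(raw))
    stop("unknown formulation key '", key, "'; available: ",
         paste(names(raw), collapse = ", "))
  entry <- raw[[key]]
  formulation(entry$label, unlist(entry$mass_fraction), catalog = catalog)
}

#' All six mimic formulations
#'
#' @return Named list of the six packaged `formulation` objects (three
#'   Mimic and three cholesterol-enriched CE Mimic compositions).
#' @export
mimic_formulations <- function() {
  keys <- load_formulation(NULL)
  stats::setNames(lapply(keys, load_formulation), keys)
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("Lipid formulation '%s' (%d species, total %.1f%%)\n",
              attr(x, "label"), nrow(x), sum(x$mass_fraction)))
  df <- as.data.frame(x)
  df$mole_fraction <- round(df$mole_fraction, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
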