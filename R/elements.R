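#' Element reference data
#'
#' Single-bond covalent radii (Angstrom) from the Pyykko & Atsumi (2009)
#' compilation, and IUPAC standard atomic weights (amu). The radii drive
#' link-atom placement factors and distance-based bond perception; both
#' tables are plain named vectors so user code can inspect or extend them
#' through the `radii` arguments of the functions that consume them.
#'
#' @name element-tables
#' @keywords internal
NULL

# Pyykko & Atsumi (2009) single-bond covalent radii, Angstrom.
.covalent_radii <- c(
  H  = 0.32, He = 0.46,
  Li = 1.33, Be = 1.02, B  = 0.85, C  = 0.75, N  = 0.71, O  = 0.63,
  F  = 0.64, Ne = 0.67,
  Na = 1.55, Mg = 1.39, Al = 1.26, Si = 1.16, P  = 1.11, S  = 1.03,
  Cl = 0.99, Ar = 0.96,
  K  = 1.96, Ca = 1.71, Sc = 1.48, Ti = 1.36, V  = 1.34, Cr = 1.22,
  Mn = 1.19, Fe = 1.16, Co = 1.11, Ni = 1.10, Cu = 1.12, Zn = 1.18,
  Ga = 1.24, Ge = 1.21, As = 1.21, Se = 1.16, Br = 1.14, Kr = 1.17,
  I  = 1.33
)

# IUPAC 2021 standard atomic weights, amu (abridged).
.atomic_masses <- c(
  H  = 1.008,   He = 4.0026,
  Li = 6.94,    Be = 9.0122,  B  = 10.81,   C  = 12.011,  N  = 14.007,
  O  = 15.999,  F  = 18.998,  Ne = 20.180,
  Na = 22.990,  Mg = 24.305,  Al = 26.982,  Si = 28.085,  P  = 30.974,
  S  = 32.06,   Cl = 35.45,   Ar = 39.948,
  K  = 39.098,  Ca = 40.078,  Sc = 44.956,  Ti = 47.867,  V  = 50.942,
  Cr = 51.996,  Mn = 54.938,  Fe = 55.845,  Co = 58.933,  Ni = 58.693,
  Cu = 63.546,  Zn = 65.38,
  Ga = 69.723,  Ge = 72.630,  As = 74.922,  Se = 78.971,  Br = 79.904,
  Kr = 83.798,  I  = 126.90
)

#' Normalize an element symbol ("c", "CL" -> "C", "Cl")
#' @noRd
normalize_element <- function(el) {
  el <- trimws(as.character(el))
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

#' Covalent radius of an element
#'
#' Looks up the single-bond covalent radius used for link-atom scale
#' factors and bond perception. Lookup is case-normalizing.
#'
#' @param element Element symbol (scalar or vector), case-insensitive.
#' @param radii Named numeric vector of radii (Angstrom) to consult;
#'   defaults to the shipped single-bond table.
#' @return Covalent radius / radii in Angstrom.
#' @examples
#' covalent_radius("H")
#' covalent_radius(c("C", "s"))
#' @export
covalent_radius <- function(element, radii = covalent_radii_table()) {
  el <- normalize_element(element)
  miss <- !(el %in% names(radii))
  if (any(miss)) {
    stop("unknown element(s) in covalent radius table: ",
         paste(unique(el[miss]), collapse = ", "), call. = FALSE)
  }
  unname(radii[el])
}

#' The shipped covalent-radius table
#'
#' @return Named numeric vector, element symbol -> single-bond covalent
#'   radius in Angstrom.
#' @export
covalent_radii_table <- function() .covalent_radii

#' Atomic mass of an element
#'
#' @param element Element symbol (scalar or vector), case-insensitive.
#' @return Standard atomic weight(s) in amu.
#' @examples
#' atomic_mass("O")
#' @export
atomic_mass <- function(element) {
  el <- normalize_element(element)
  miss <- !(el %in% names(.atomic_masses))
  if (any(miss)) {
    stop("unknown element(s) in mass table: ",
         paste(unique(el[miss]), collapse = ", "), call. = FALSE)
  }
  unname(.atomic_masses[el])
}

# Physical constants (CODATA 2018 / SI exact where defined).
.const <- list(
  hartree_kcal = 627.509474,        # 1 Hartree in kcal/mol
  hartree_J    = 4.3597447222071e-18,
  amu_kg       = 1.66053906660e-27,
  h            = 6.62607015e-34,    # J s
  kB           = 1.380649e-23,      # J / K
  c_cm         = 2.99792458e10,     # cm / s
  Avogadro     = 6.02214076e23,
  R            = 8.314462618,       # J / mol / K
  cal_J        = 4.184,
  atm_Pa       = 101325
)

#' Unit conversion: Hartree to kcal/mol
#' @param x Energy in Hartree.
#' @return Energy in kcal/mol.
#' @export
hartree_to_kcal <- function(x) x * .const$hartree_kcal
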