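# Physical constants and default force-field style tables.
# Units throughout the package: lengths in Angstrom, times in ps,
# energies in kcal/mol, charges in elementary charge e, temperatures in K.

#' Coulomb constant in AMBER units
#'
#' Electrostatic conversion factor, 332.0636 kcal * Angstrom / (mol * e^2).
#' @keywords internal
KCOUL <- 332.0636

#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
KBOLTZ <- 1.9872041e-3

# Default interior dielectric per residue polarity class.
.default_dielectrics <- c(nonpolar = 1, polar = 3, charged = 10)

# Residue polarity classification (sidechain chemistry; protonation
# variants included). TYR/TRP are kept polar by default; see
# classify_residue() docs.
.polarity_table <- c(
  ASP = "charged", GLU = "charged", LYS = "charged", ARG = "charged",
  HIP = "charged",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
  HIS = "polar", HIE = "polar", HID = "polar",
  TYR = "polar", TRP = "polar", CYS = "polar",
  ASH = "polar", GLH = "polar", LYN = "polar",
  ALA = "nonpolar", VAL = "nonpolar", LEU = "nonpolar", ILE = "nonpolar",
  PRO = "nonpolar", PHE = "nonpolar", MET = "nonpolar", GLY = "nonpolar",
  CYX = "nonpolar"
)

# Standard atomic masses (amu) for center-of-mass weights.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845
)

# mbondi2-style intrinsic Born radii (Angstrom) by element; hydrogens
# bonded to nitrogen get 1.3 instead of 1.2 (resolved by atom name).
.gb_radius_by_element <- c(
  H = 1.2, C = 1.7, N = 1.55, O = 1.5, F = 1.5,
  P = 1.85, S = 1.8, CL = 1.7, BR = 1.85, I = 1.98
)

# GB descreening (scaling) factors by element, igb = 2 convention.
.gb_screen_by_element <- c(
  H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96, P = 0.86
)

# Alanine methyl parameters used when a sidechain is truncated to Cbeta:
# CT carbon and HC hydrogens with standard alanine library charges.
.ala_methyl <- list(
  cb = list(charge = -0.1825, rmin_half = 1.9080, epsilon = 0.1094,
            gb_radius = 1.7, gb_screen = 0.72),
  hb = list(charge = 0.0603, rmin_half = 1.4870, epsilon = 0.0157,
            gb_radius = 1.2, gb_screen = 0.85)
)

#' Default intrinsic Born radius and screening factor for an atom
#'
#' mbondi2-style assignment by element, with the hydrogen-on-nitrogen
#' special case resolved from the atom name (H, H1..H3, HN* are treated
#' as amide/amine hydrogens).
#'
#' @param element element symbol (e.g. "C", "H").
#' @param name atom name (PDB convention), used only for hydrogens.
#' @return list with `gb_radius` and `gb_screen`.
#' @export
default_gb_params <- function(element, name = "") {
  el <- toupper(element)
  r <- unname(.gb_radius_by_element[el])
  if (is.na(r)) r <- 1.5
  if (el == "H" && grepl("^(H|H[123]|HN.*)$", toupper(name))) r <- 1.3
  s <- unname(.gb_screen_by_element[el])
  if (is.na(s)) s <- 0.8
  list(gb_radius = r, gb_screen = s)
}

#' Atomic mass lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in amu; unknown elements error.
#' @export
atomic_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
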