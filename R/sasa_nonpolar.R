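# Solvent-accessible surface area (Shrake-Rupley with a deterministic
# Fibonacci-spiral point set) and the empirical nonpolar solvation term
# dG_np = gamma * SASA + beta.

#' Deterministic Fibonacci-spiral points on the unit sphere
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_points <- function(n) {
  i <- seq_len(n) - 1
  ga <- pi * (3 - sqrt(5)) # golden angle
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  th <- i * ga
  cbind(r * cos(th), r * sin(th), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere of radius `r_i + probe` is sampled with a shared
#' deterministic point set; points occluded by any neighbor sphere
#' (radius `r_j + probe`) are removed, and the accessible fraction is
#' scaled to the sphere area.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom radii (Angstrom), > 0.
#' @param probe probe radius (default 1.4 Angstrom).
#' @param n_points sampling points per atom (default 960, >= 32).
#' @return `SasaResult`: list with `per_atom_sasa`, `total`,
#'   `probe_radius`, `n_sphere_points`.
#' @export
shrake_rupley_sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  n <- length(radii)
  stopifnot(nrow(coords) == n, all(radii > 0), n_points >= 32)
  pts <- fibonacci_points(n_points)
  rext <- radii + probe
  per_atom <- numeric(n)
  d <- if (n > 1L) .cross_dist(coords, coords) else matrix(0, 1, 1)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rext[i] + rext & seq_len(n) != i)
    if (length(nb) == 0L) {
      frac <- 1
    } else {
      p <- sweep(pts * rext[i], 2, coords[i, ], "+")
      occluded <- rep(FALSE, n_points)
      for (j in nb) {
        dp2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
          (p[, 3] - coords[j, 3])^2
        occluded <- occluded | dp2 < rext[j]^2
        if (all(occluded)) break
      }
      frac <- mean(!occluded)
    }
    per_atom[i] <- 4 * pi * rext[i]^2 * frac
  }
  structure(list(per_atom_sasa = per_atom, total = sum(per_atom),
                 probe_radius = probe, n_sphere_points = n_points),
            class = "SasaResult")
}

#' Empirical nonpolar solvation free energy
#'
#' `dG_np = gamma * SASA + beta` with gamma = 0.00542 kcal/(mol A^2)
#' and beta = 0.92 kcal/mol by default.
#'
#' @param sasa_total total SASA in A^2 (>= 0).
#' @param gamma surface tension coefficient, kcal/(mol A^2).
#' @param beta offset, kcal/mol.
#' @return energy in kcal/mol.
#' @export
nonpolar_energy <- function(sasa_total, gamma = 0.00542, beta = 0.92) {
  if (any(sasa_total < 0)) stop("SASA must be non-negative")
  gamma * sasa_total + beta
}

#' Nonpolar complexation energy from species SASA totals
#'
#' `dG_np(complexation) = G_np(complex) - G_np(protein) - G_np(ligand)
#'  = gamma * (S_c - S_p - S_l) - beta`. The beta offsets cancel in
#' wild-vs-mutant differences.
#'
#' @param complex_sasa,protein_sasa,ligand_sasa SASA totals in A^2.
#' @inheritParams nonpolar_energy
#' @return energy in kcal/mol.
#' @export
delta_np <- function(complex_sasa, protein_sasa, ligand_sasa,
                     gamma = 0.00542, beta = 0.92) {
  nonpolar_energy(complex_sasa, gamma, beta) -
    nonpolar_energy(protein_sasa, gamma, beta) -
    nonpolar_energy(ligand_sasa, gamma, beta)
}

#' SASA of a species (atom subset) of a system
#'
#' Radii default to the Lennard-Jones Rmin/2 values stored on the
#' system.
#'
#' @param sys parameterized ParamSystem.
#' @param coords full-system frame.
#' @param atoms atom indices of the species.
#' @param probe probe radius (Angstrom).
#' @param n_points sampling points per atom.
#' @param radii optional per-atom radii over all system atoms.
#' @return total SASA in A^2.
#' @export
sasa_species <- function(sys, coords, atoms, probe = 1.4, n_points = 960,
                         radii = NULL) {
  if (is.null(radii)) radii <- sys$atoms$rmin_half
  shrake_rupley_sasa(coords[atoms, , drop = FALSE], radii[atoms],
                     probe, n_points)$total
}

#' Nonpolar complexation energy for one frame of a system
#'
#' @inheritParams sasa_species
#' @inheritParams nonpolar_energy
#' @return list with species SASAs and `delta` (kcal/mol).
#' @export
np_delta_solvation <- function(sys, coords, probe = 1.4, n_points = 960,
                               gamma = 0.00542, beta = 0.92, radii = NULL) {
  lig <- ligand_atoms(sys)
  all_at <- seq_len(nrow(sys$atoms))
  prot <- setdiff(all_at, lig)
  sc <- sasa_species(sys, coords, all_at, probe, n_points, radii)
  sp <- sasa_species(sys, coords, prot, probe, n_points, radii)
  sl <- sasa_species(sys, coords, lig, probe, n_points, radii)
  list(complex = sc, protein = sp, ligand = sl,
       delta = delta_np(sc, sp, sl, gamma, beta))
}
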